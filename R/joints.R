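# Tracked joint set and motion-task definitions.

.rom_sides <- c("left", "right")
.rom_joint_labels <- c("wrist", "elbow", "shoulder", "hip", "knee", "ankle")

#' Tracked joint names
#'
#' The twelve body joints tracked by the pipeline: wrist, elbow, shoulder,
#' hip, knee and ankle on each side. Joint names are fixed snake_case
#' `side_joint` strings (e.g. `"right_elbow"`) across all files and APIs.
#'
#' @return Character vector of the 12 joint names.
#' @export
#' @examples
#' joint_names()
joint_names <- function() {
  as.vector(t(outer(.rom_sides, .rom_joint_labels, paste, sep = "_")))
}

#' @rdname joint_names
#' @param joint A joint name to split into side and anatomical label.
#' @return `joint_side_label()`: a list with elements `side` and `label`.
#' @export
joint_side_label <- function(joint) {
  if (!joint %in% joint_names()) {
    rom_input_error(sprintf("unknown joint name '%s'", joint))
  }
  parts <- strsplit(joint, "_", fixed = TRUE)[[1]]
  list(side = parts[1], label = parts[2])
}

#' Supported motion tasks
#'
#' Three upper-extremity range-of-motion tasks are supported. Each maps to
#' exactly one angle definition (see [angle_definition()]) and one canonical
#' camera view: shoulder abduction is filmed from the anterior view, both
#' flexion tasks from the lateral view on the moving side.
#'
#' @return Character vector of task names.
#' @export
motion_tasks <- function() {
  c("shoulder_abduction", "shoulder_flexion", "elbow_flexion")
}

match_task <- function(task) {
  match_choice(task, motion_tasks(), "task")
}

match_choice <- function(value, choices, what) {
  if (length(value) != 1 || !value %in% choices) {
    rom_input_error(sprintf("%s must be one of: %s", what,
                            paste(choices, collapse = ", ")))
  }
  value
}

#' Camera view associated with a motion task
#'
#' @param task One of [motion_tasks()].
#' @return `"anterior"` or `"lateral"`.
#' @export
task_view <- function(task) {
  task <- match_task(task)
  if (task == "shoulder_abduction") "anterior" else "lateral"
}

#' Angle definition for a motion task
#'
#' Every task measures the angle at a vertex joint B between two rays BA and
#' BC. Shoulder tasks place the vertex at the shoulder with BA the
#' shoulder-to-elbow vector and BC the shoulder-to-hip vector; the raw angle
#' is reported as-is. Elbow flexion places the vertex at the elbow with BA
#' the elbow-to-wrist vector and BC the elbow-to-shoulder vector, and
#' reports the supplement (180 degrees minus the raw angle) so that full
#' extension reads 0 degrees.
#'
#' @param task One of [motion_tasks()].
#' @param side `"left"` or `"right"`; resolves joint roles to joint names.
#' @return A list with elements `vertex`, `ray_a_end`, `ray_c_end` (joint
#'   names) and `transform` (`"identity"` or `"supplement"`).
#' @export
#' @examples
#' angle_definition("elbow_flexion", "right")
angle_definition <- function(task, side = c("right", "left")) {
  task <- match_task(task)
  side <- match.arg(side)
  def <- switch(task,
    shoulder_abduction = ,
    shoulder_flexion = list(vertex = "shoulder", ray_a_end = "elbow",
                            ray_c_end = "hip", transform = "identity"),
    elbow_flexion = list(vertex = "elbow", ray_a_end = "wrist",
                         ray_c_end = "shoulder", transform = "supplement")
  )
  def$vertex <- paste(side, def$vertex, sep = "_")
  def$ray_a_end <- paste(side, def$ray_a_end, sep = "_")
  def$ray_c_end <- paste(side, def$ray_c_end, sep = "_")
  def
}
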