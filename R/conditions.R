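# Structured conditions: every user-facing failure carries a subclass so the
# CLI can map it onto an exit code (input/config/format/io -> 2, else 1).

rom_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "rom_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

rom_input_error <- function(message) rom_error(message, "rom_input_error")
rom_config_error <- function(message) rom_error(message, "rom_config_error")
rom_format_error <- function(message) rom_error(message, "rom_format_error")
rom_io_error <- function(message) rom_error(message, "rom_io_error")
rom_insufficient_data_error <- function(message) {
  rom_error(message, c("rom_insufficient_data_error", "rom_input_error"))
}
rom_degenerate_error <- function(message) {
  rom_error(message, c("rom_degenerate_error", "rom_input_error"))
}
rom_undefined_stat_error <- function(message) {
  rom_error(message, c("rom_undefined_stat_error", "rom_input_error"))
}

#' @noRd
is_rom_user_error <- function(cond) {
  inherits(cond, c("rom_input_error", "rom_config_error",
                   "rom_format_error", "rom_io_error"))
}
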