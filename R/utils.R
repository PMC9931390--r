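#' @keywords internal
gs_assert <- function(cond, msg, class = "gemscreen_input_error") {
  if (!isTRUE(cond)) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  invisible(TRUE)
}

#' @keywords internal
gs_warn <- function(msg) warning(msg, call. = FALSE)

# Positive scalar check used by the config validators
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_pos_num <- function(x) is_scalar_num(x) && x > 0

is_count <- function(x) is_scalar_num(x) && x >= 1 && x == floor(x)
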