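# internal validation helpers

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "abidecode_config_error")
}

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "abidecode_input_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config("`%s` must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_config("`%s` = %g is outside its valid range", name, x)
  }
  invisible(x)
}

# pull a numeric sample vector plus sampling rate out of the accepted
# input forms: an ae_recording / decoded / envelope tibble, any data frame
# with a voltage-like column, or a bare numeric vector with fs supplied
resolve_trace <- function(x, fs = NULL,
                          cols = c("voltage", "amplitude", "signal", "value")) {
  if (is.data.frame(x)) {
    col <- intersect(cols, names(x))
    if (length(col) == 0L) {
      stop_input("no sample column found; expected one of: %s",
                 paste(cols, collapse = ", "))
    }
    samples <- x[[col[[1L]]]]
    fs <- fs %||% attr(x, "fs")
    if (is.null(fs)) stop_input("sampling rate `fs` missing from `%s`", col[[1L]])
  } else if (is.numeric(x)) {
    samples <- as.numeric(x)
    if (is.null(fs)) stop_input("`fs` must be supplied with a bare numeric trace")
  } else {
    stop_input("cannot interpret object of class <%s> as a trace",
               paste(class(x), collapse = "/"))
  }
  if (length(samples) == 0L) stop_input("trace is empty")
  if (!all(is.finite(samples))) stop_input("trace contains non-finite samples")
  list(samples = samples, fs = as.numeric(fs))
}

new_ae_tibble <- function(df, class, ...) {
  out <- tibble::as_tibble(df)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(class, class(out))
  out
}

# reattach attributes/class lost by dplyr verbs
rebuild_like <- function(df, template, class) {
  keep <- setdiff(names(attributes(template)),
                  c("names", "row.names", "class"))
  for (nm in keep) attr(df, nm) <- attr(template, nm)
  class(df) <- c(class, setdiff(class(df), class))
  df
}
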