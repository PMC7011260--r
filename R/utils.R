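# Internal numerical helpers shared by the credibility routines.

# log(exp(a) + exp(b)) without leaving log space; tolerates -Inf.
logspace_add <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Column lookup with a default, without tibble's unknown-column warning.
col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else rep(default, nrow(df))
}

# Vectorised argument check with a caller-friendly message.
check_range <- function(x, name, lower = -Inf, upper = Inf,
                        open_lower = TRUE, open_upper = TRUE,
                        allow_na = FALSE) {
  bad <- if (open_lower) x <= lower else x < lower
  bad <- bad | if (open_upper) x >= upper else x > upper
  if (allow_na) bad[is.na(x)] <- FALSE else bad[is.na(x)] <- TRUE
  if (any(bad)) {
    stop(sprintf("`%s` out of range %s%s, %s%s at position(s) %s",
                 name,
                 if (open_lower) "(" else "[", format(lower),
                 format(upper), if (open_upper) ")" else "]",
                 paste(head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
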