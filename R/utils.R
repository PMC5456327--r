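## Internal helpers: logging, validation, deterministic ordering.

#' Pipeline logging
#'
#' Filtering and rejection steps report their record counts through a single
#' logging channel so the reduction funnel (raw rows, mapped, collapsed,
#' thresholded, consensus) stays auditable on any input. Messages are emitted
#' with [rlang::inform()] and can be silenced with
#' `options(fabrymeta.verbose = FALSE)`.
#'
#' @param stage short stage label.
#' @param ... sprintf-style message parts, pasted together.
#' @keywords internal
fm_log <- function(stage, ...) {
  if (isFALSE(getOption("fabrymeta.verbose", TRUE))) {
    return(invisible(NULL))
  }
  inform(paste0("[", stage, "] ", paste0(..., collapse = "")),
         class = "fabrymeta_log")
  invisible(NULL)
}

## stop with a classed condition so callers (and the CLI) can distinguish
## configuration errors from malformed data.
fm_abort <- function(message, class) {
  abort(message, class = c(class, "fabrymeta_error"))
}

fm_config_error <- function(message) fm_abort(message, "fabrymeta_config_error")
fm_format_error <- function(message) fm_abort(message, "fabrymeta_format_error")
fm_validation_error <- function(message) fm_abort(message, "fabrymeta_validation_error")
fm_reference_error <- function(message) fm_abort(message, "fabrymeta_reference_error")
fm_domain_error <- function(message) fm_abort(message, "fabrymeta_domain_error")

## check that a data frame carries the named columns; error names the missing
fm_require_columns <- function(df, columns, what) {
  missing <- setdiff(columns, names(df))
  if (length(missing) > 0) {
    fm_format_error(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

fm_check_vocab <- function(x, vocab, what, where) {
  bad <- setdiff(unique(x), vocab)
  if (length(bad) > 0) {
    fm_format_error(sprintf(
      "%s: unknown %s value%s: %s (allowed: %s)",
      where, what, if (length(bad) > 1) "s" else "",
      paste(bad, collapse = ", "), paste(vocab, collapse = ", ")
    ))
  }
  invisible(x)
}

## scalar checks used by the statistics layer
fm_check_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x != as.integer(x)) {
    fm_domain_error(sprintf("`%s` must be a single non-negative integer", name))
  }
  as.integer(x)
}

## Fold-change magnitude: max(r, 1/r) for a positive ratio. The up/down
## direction convention lives in fm_direction().
fc_magnitude <- function(ratio) pmax(ratio, 1 / ratio)

## ratio > 1 is up, otherwise down (ratios are strictly positive; exact 1
## counts as down and never survives any fold-change threshold anyway).
fm_direction <- function(ratio) ifelse(ratio > 1, "up", "down")
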