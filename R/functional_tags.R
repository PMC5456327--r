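## Functionality-tag composition summaries per patient group, split by
## regulation direction, with exclusivity detection.

## half-up rounding to one decimal (avoids R's round-half-even so that the
## reported percentages match conventional presentation)
fm_round_pct <- function(x) floor(x * 10 + 0.5) / 10

#' Summarise functionality-tag composition of a consensus set
#'
#' Counts consensus features per coarse functionality tag within one patient
#' group, split by regulation direction. `pct_total` is the tag's share of
#' all features in the group; `pct_up` / `pct_down` are its shares of the
#' group's up- and down-regulated features respectively (0 when the group has
#' none in that direction). A tag is `all_up` when every one of its features
#' is up-regulated, `all_down` symmetrically, `mixed` otherwise. Percentages
#' are reported to one decimal, half-up.
#'
#' @param consensus consensus feature tibble (see [consistency_merge()])
#'   carrying `tag` and `direction` columns.
#' @param group patient group label recorded in the output (taken from the
#'   data when omitted).
#' @return tibble with one row per tag present, sorted by descending
#'   `pct_total` then tag code.
#' @export
summarize_tags <- function(consensus, group = NULL) {
  fm_require_columns(consensus, c("tag", "direction"), "consensus features")
  if (!is.null(group)) {
    group <- match.arg(group, fm_groups)
    if ("group" %in% names(consensus)) {
      consensus <- consensus[consensus$group == group, , drop = FALSE]
    }
  } else {
    group <- if ("group" %in% names(consensus) && nrow(consensus) > 0)
      consensus$group[1] else NA_character_
  }
  if (nrow(consensus) == 0) {
    fm_validation_error("no features to summarise for this group")
  }
  n_group <- nrow(consensus)
  n_up_group <- sum(consensus$direction == "up")
  n_down_group <- sum(consensus$direction == "down")
  out <- dplyr::summarise(
    dplyr::group_by(consensus, .data$tag),
    n_total = dplyr::n(),
    n_up = sum(.data$direction == "up"),
    n_down = sum(.data$direction == "down"),
    .groups = "drop"
  )
  out$group <- group
  out$pct_total <- fm_round_pct(100 * out$n_total / n_group)
  out$pct_up <- if (n_up_group > 0) fm_round_pct(100 * out$n_up / n_up_group) else 0
  out$pct_down <- if (n_down_group > 0)
    fm_round_pct(100 * out$n_down / n_down_group) else 0
  out$exclusivity <- dplyr::case_when(
    out$n_down == 0 & out$n_up > 0 ~ "all_up",
    out$n_up == 0 & out$n_down > 0 ~ "all_down",
    TRUE ~ "mixed"
  )
  out <- out[order(-out$pct_total, out$tag),
             c("group", "tag", "n_total", "n_up", "n_down",
               "pct_total", "pct_up", "pct_down", "exclusivity")]
  tibble::as_tibble(out)
}
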