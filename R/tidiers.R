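#' Tidy the per-transcript cascade outcome
#'
#' @param x A `lnc_cascade`.
#' @param ... Unused.
#' @return Tibble `(transcript_id, pass, reason)`.
#' @export
tidy.lnc_cascade <- function(x, ...) {
  x$detail
}

#' One-row cascade funnel summary
#'
#' @param x A `lnc_cascade`.
#' @param ... Unused.
#' @return One-row tibble: input size, survivors, and `out_<stage>` counts.
#' @export
glance.lnc_cascade <- function(x, ...) {
  wide <- x$report |>
    mutate(stage = paste0("out_", .data$stage)) |>
    select("stage", "n_out") |>
    pivot_wider(names_from = "stage", values_from = "n_out")
  bind_cols(
    tibble::tibble(n_input = if (nrow(x$report) > 0) x$report$n_in[1] else 0L,
                   n_survivors = nrow(x$survivors)),
    wide
  )
}

#' Tidy a differential-expression table
#'
#' @param x A `lnc_de`.
#' @param ... Unused.
#' @return The underlying tibble, unclassed.
#' @export
tidy.lnc_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "lnc_de")
  out
}

#' One-row differential-expression summary
#'
#' @param x A `lnc_de`.
#' @param ... Unused.
#' @return One-row tibble with mode, thresholds in use and call counts.
#' @export
glance.lnc_de <- function(x, ...) {
  tab <- table(x$call)
  tibble::tibble(
    mode = attr(x, "mode"),
    n = nrow(x),
    n_up_in_mt = as.integer(tab[["up_in_MT"]]),
    n_down_in_mt = as.integer(tab[["down_in_MT"]]),
    n_not_significant = as.integer(tab[["not_significant"]]),
    n_filtered = as.integer(tab[["filtered"]])
  )
}

#' Tidy classification output alongside planted truth
#'
#' @param x A `lnc_run`.
#' @param ... Unused.
#' @return The evaluation tibble from [validate_against_truth()].
#' @export
tidy.lnc_run <- function(x, ...) {
  validate_against_truth(x)
}
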