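#' Broom-style tidiers for parentage results
#'
#' `tidy()` flattens a parentage table to plain atomic columns (positions
#' comma-joined, candidate lists collapsed to `species:count` strings), ready
#' for `readr::write_tsv()`. `glance()` reduces it to a one-row overview.
#'
#' @param x an `ht_parentage` tibble from [infer_parentage()].
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.ht_parentage <- function(x, ...) {
  out <- .format_calls_tsv(x)
  class(out) <- setdiff(class(out), "ht_parentage")
  out
}

#' @rdname tidy.ht_parentage
#' @exportS3Method generics::glance
glance.ht_parentage <- function(x, ...) {
  hyb <- x$verdict %in% c("F1_HYBRID", "COMPLEX_HYBRID")
  tibble::tibble(
    n_samples = nrow(x),
    n_species = sum(x$verdict == "SPECIES"),
    n_f1 = sum(x$verdict == "F1_HYBRID"),
    n_complex = sum(x$verdict == "COMPLEX_HYBRID"),
    n_unresolved = sum(x$verdict == "UNRESOLVED"),
    mean_additive = if (any(hyb)) mean(x$n_additive[hyb]) else NA_real_,
    mean_residual = if (any(hyb)) mean(x$n_residual[hyb]) else NA_real_
  )
}

#' @rdname tidy.ht_parentage
#' @exportS3Method generics::glance
glance.ht_survey <- function(x, ...) {
  g <- glance.ht_parentage(x$calls)
  g$n_oriented <- sum(x$crosses$confidence == "ORIENTED")
  g$fraction_focal_paternal <- if (is.null(x$directionality)) NA_real_ else
    x$directionality$fraction_paternal
  g
}
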