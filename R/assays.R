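# Closed-form assay computations: relative qPCR quantification by the
# 2^-ddCt method and percent suppression from proliferation fractions.

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = ct_target - ct_reference`; `ddCt` subtracts the
#' median `dCt` of the control group; the relative quantity is
#' `RQ = 2^-ddCt` (so the control-group median RQ is 1 when the control
#' size is odd). Duplicate wells should be averaged on the Ct scale before
#' calling this.
#'
#' @param measurements data.frame with columns `sample_id`, `group`,
#'   `ct_target`, `ct_reference`.
#' @param control_group label of the reference group (e.g. `"naive"`).
#' @return The input with added columns `dct`, `ddct`, `rq`.
#' @examples
#' df <- data.frame(sample_id = c("a", "b", "c"),
#'                  group = c("ctrl", "ctrl", "ctrl"),
#'                  ct_target = c(25, 26, 24), ct_reference = c(20, 20, 20))
#' relative_quantity(df, "ctrl")$rq
#' @export
relative_quantity <- function(measurements, control_group) {
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  ctrl <- measurements$group == control_group
  if (!any(ctrl)) stop("empty control group", call. = FALSE)
  dct <- measurements$ct_target - measurements$ct_reference
  ddct <- dct - stats::median(dct[ctrl])
  measurements$dct <- dct
  measurements$ddct <- ddct
  measurements$rq <- 2^(-ddct)
  measurements
}

#' Percent suppression of effector T-cell proliferation
#'
#' Proliferation in coculture is expressed as a percentage of the
#' proliferation of effector cells alone; suppression is its complement:
#' `100 * (1 - cocultured/alone)`. May be negative if the coculture
#' proliferates more than the cells alone.
#'
#' @param alone proliferating fraction of effector cells cultured alone
#'   (must be > 0).
#' @param cocultured proliferating fraction in the presence of Tregs.
#' @return Percent suppression (vectorized).
#' @examples
#' percent_suppression(0.8, 0.4)  # 50
#' @export
percent_suppression <- function(alone, cocultured) {
  if (any(alone <= 0))
    stop("proliferating fraction alone must be > 0", call. = FALSE)
  if (any(alone > 1 | cocultured > 1 | cocultured < 0))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  100 - 100 * cocultured / alone
}
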