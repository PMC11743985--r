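#' Dynamic pain connectome ROI atlas
#'
#' Sixteen regions of interest spanning the four networks/pathways of the
#' dynamic pain connectome (DPC): the ascending nociceptive pathway, the
#' descending antinociceptive pathway, the salience network, and the default
#' mode network. Coordinates are MNI152 (x, y, z) in millimetres.
#'
#' These are the nodes over which the spectral metrics are tabulated and the
#' multiple-comparison family (16 tests per metric per contrast) is defined.
#'
#' @return A `data.frame` with columns `roi`, `network`, `x`, `y`, `z`
#'   (16 rows).
#' @examples
#' atlas <- dpc_atlas()
#' table(atlas$network)
#' @export
dpc_atlas <- function() {
  asc <- "ascending_nociceptive"
  des <- "descending_antinociceptive"
  sal <- "salience"
  dmn <- "default_mode"
  out <- data.frame(
    roi = c("left_thalamus", "right_thalamus",
            "left_S1", "right_S1",
            "left_S2", "right_S2",
            "left_posterior_insula", "right_posterior_insula",
            "sgACC",
            "right_TPJ", "right_anterior_insula", "MCC", "right_dlPFC",
            "PCC", "mPFC", "precuneus"),
    network = c(rep(asc, 8L), des, rep(sal, 4L), rep(dmn, 3L)),
    x = c(-12, 12, -34, 34, -60, 60, -34, 34, 4, 50, 34, 2, 34, -2, -2, 2),
    y = c(-18, -18, -30, -28, -30, -22, -20, -20, 26, -32, 18, 12, 46,
          -46, 50, -61),
    z = c(8, 8, 54, 54, 20, 18, 18, 18, -8, 28, 4, 34, 22, 28, 2, 48),
    stringsAsFactors = FALSE
  )
  out
}
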