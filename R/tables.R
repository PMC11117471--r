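#' Published benchmark table rows used as worked examples
#'
#' Performance indicators reported by a published lung-nodule detection
#' benchmark study on LUNA16: four backbone classifiers (ResNet, DenseNet,
#' MobileNet, MixNet) under k-means and fuzzy c-means anchor clustering with
#' cluster counts K in {3, 5, 7, 9}, plus attention-model variants (SENet,
#' CA-I, CA-II) for the two strongest backbones. These rows serve as worked
#' examples for the F1 identity: the printed F1 cell should equal the
#' harmonic mean of the printed precision and sensitivity up to the rounding
#' of the inputs.
#'
#' @return A tibble with columns `table` (1-10), `backbone`, `clustering`,
#'   `setting` (cluster count or attention variant), `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`.
#' @export
nodule_benchmark_tables <- function() {
  rows <- function(tab, backbone, clustering, settings, acc, prec, sens, spec, f1) {
    tibble::tibble(table = tab, backbone = backbone, clustering = clustering,
                   setting = settings, accuracy = acc, precision = prec,
                   sensitivity = sens, specificity = spec, f1 = f1)
  }
  ks <- c("K=3", "K=5", "K=7", "K=9")
  att <- c("none", "SENet", "CA-I", "CA-II")
  dplyr::bind_rows(
    rows(1L, "ResNet", "kmeans", ks,
         c(.9287, .9389, .9430, .9409), c(.9146, .9265, .9342, .9339),
         c(.9414, .9498, .9498, .9456), c(.9167, .9286, .9365, .9365),
         c(.9278, .9380, .9419, .9397)),
    rows(2L, "ResNet", "fcm", ks,
         c(.9348, .9491, .9450, .9389), c(.9259, .9421, .9380, .9336),
         c(.9414, .9540, .9498, .9414), c(.9286, .9444, .9405, .9365),
         c(.9336, .9480, .9439, .9375)),
    rows(3L, "DenseNet", "kmeans", ks,
         c(.9145, .9430, .9369, .9348), c(.8988, .9342, .9298, .9259),
         c(.9289, .9498, .9414, .9414), c(.9008, .9365, .9325, .9286),
         c(.9136, .9419, .9356, .9336)),
    rows(4L, "DenseNet", "fcm", ks,
         c(.9287, .9491, .9409, .9328), c(.9180, .9385, .9339, .9256),
         c(.9372, .9582, .9456, .9372), c(.9206, .9405, .9365, .9286),
         c(.9275, .9482, .9397, .9314)),
    rows(5L, "MobileNet", "kmeans", ks,
         c(.9104, .9226, .9226, .9206), c(.8980, .9069, .9136, .9098),
         c(.9205, .9272, .9289, .9289), c(.9008, .9087, .9167, .9127),
         c(.9091, .9218, .9212, .9193)),
    rows(6L, "MobileNet", "fcm", ks,
         c(.9435, .9300, .9300, .9246), c(.9020, .8582, .8610, .8533),
         c(.9247, .9372, .9331, .9247), c(.9524, .9266, .9286, .9246),
         c(.9132, .8960, .8956, .8876)),
    rows(7L, "MixNet", "kmeans", ks,
         c(.9206, .9369, .9348, .9308), c(.9132, .9298, .9295, .9218),
         c(.9247, .9414, .9372, .9372), c(.9167, .9325, .9325, .9246),
         c(.9189, .9356, .9333, .9295)),
    rows(8L, "MixNet", "fcm", ks,
         c(.9246, .9381, .9367, .9314), c(.8479, .8726, .8721, .8615),
         c(.9331, .9456, .9414, .9372), c(.9206, .9345, .9345, .9286),
         c(.8884, .9076, .9054, .8978)),
    rows(9L, "ResNet", "fcm K=5", att,
         c(.9491, .9511, .9532, .9470), c(.9421, .9461, .9463, .9419),
         c(.9540, .9540, .9582, .9498), c(.9444, .9484, .9484, .9444),
         c(.9480, .9500, .9522, .9458)),
    rows(10L, "DenseNet", "fcm K=5", att,
         c(.9491, .9409, .9532, .9450), c(.9385, .9268, .9426, .9344),
         c(.9582, .9540, .9623, .9540), c(.9405, .9286, .9444, .9365),
         c(.9482, .9402, .9524, .9441))
  )
}

#' Check the F1 identity on benchmark table rows
#'
#' Recomputes F1 as the harmonic mean of each row's printed precision and
#' sensitivity and compares it with the printed F1 cell at the given
#' tolerance (which allows for the rounding of the inputs to 4 decimals).
#'
#' @param table_rows A tibble like [nodule_benchmark_tables()] (the default).
#' @param tol Absolute tolerance, default 1e-4.
#' @return The input with added columns `f1_recomputed`, `abs_diff`, `pass`.
#' @export
check_f1_consistency <- function(table_rows = nodule_benchmark_tables(),
                                 tol = 1e-4) {
  table_rows |>
    dplyr::mutate(
      f1_recomputed = f1_from_pr(.data$precision, .data$sensitivity),
      abs_diff = abs(.data$f1_recomputed - .data$f1),
      pass = .data$abs_diff <= tol + 1e-12
    )
}
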