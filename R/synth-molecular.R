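# Synthetic qPCR Cq tables with known fold-change ground truth.

#' Generate a Cq table with known fold changes
#'
#' For each sample, the reference-gene Cq is \code{cq_ref} plus measurement
#' noise, and the target-gene Cq is \code{cq_ref - log2(fold)} plus noise,
#' so the group's true 2^-ddCq (relative to a reference group with fold 1,
#' or to any stated reference group) equals the requested fold. Technical
#' duplicates (or more) are emitted per (sample, gene).
#'
#' @param true_fold_changes Named numeric vector: group -> true fold (> 0).
#' @param cq_ref Reference-gene Cq level (cycles).
#' @param noise_sd Per-measurement Gaussian Cq noise (cycles).
#' @param duplicates Technical replicates per (sample, gene); 2 matches the
#'   measured-as-duplicate-then-averaged convention.
#' @param n_per_group Biological samples per group.
#' @param seed Integer seed.
#' @return A \code{data.frame} with columns \code{sample}, \code{group},
#'   \code{gene}, \code{replicate}, \code{cq}, suitable for
#'   \code{\link{ddcq}}.
#' @export
make_cq_table <- function(true_fold_changes, cq_ref = 24, noise_sd = 0,
                          duplicates = 2, n_per_group = 7, seed = 1L) {
  stopifnot(all(true_fold_changes > 0), !is.null(names(true_fold_changes)),
            duplicates >= 1, n_per_group >= 1, noise_sd >= 0)
  with_seed(seed, {
    rows <- list()
    for (g in names(true_fold_changes)) {
      for (s in seq_len(n_per_group)) {
        sid <- sprintf("%s_s%02d", g, s)
        for (gene in c("target", "reference")) {
          mu <- if (gene == "target")
            cq_ref - log2(true_fold_changes[[g]]) else cq_ref
          for (r in seq_len(duplicates)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample = sid, group = g, gene = gene, replicate = r,
              cq = mu + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}
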