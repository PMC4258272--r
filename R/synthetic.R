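#' Specification for a paired synthetic transcriptome experiment
#'
#' Describes the statistical structure the ordination method assumes:
#' a handful of cell classes, each with a disjoint set of marker genes
#' raised by a fixed effect over a common baseline, few replicates per
#' class, and small within-class Gaussian noise relative to the
#' between-class effect. The defaults (1000 genes, 4 helper-T-like
#' classes, 25 markers per class, effect 4 on a log2-like scale, noise
#' SD 1, duplicate samples per class) mimic a typical curated reference
#' panel of differentiated subsets profiled in duplicate.
#'
#' @param n_genes total number of genes.
#' @param classes character vector of class labels.
#' @param markers_per_class number of marker genes per class (marker
#'   sets are disjoint).
#' @param replicates_resource,replicates_test replicate samples per
#'   class in the resource and test datasets.
#' @param effect_size expression units added to a class's markers in
#'   samples of that class (> 0).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (>= 0).
#' @param baseline_mean baseline expression level (>= 0); values are
#'   clipped at 0 after noise.
#' @param knockout optional `list(class = <label>,
#'   fraction_of_markers_silenced = <0..1>)`: in the *test* dataset an
#'   extra class `<label>.KO` is added whose silenced markers lose the
#'   effect (emulating a transcription-factor knockout that fails to
#'   induce its programme).
#' @param seed integer seed; generation is fully reproducible.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000,
                           classes = c("Th1", "Th2", "Th17", "iTreg"),
                           markers_per_class = 25,
                           replicates_resource = 2,
                           replicates_test = 2,
                           effect_size = 4,
                           noise_sd = 1,
                           baseline_mean = 4,
                           knockout = NULL,
                           seed = 1) {
  if (length(classes) * markers_per_class > n_genes) {
    stop("marker budget exceeds n_genes: ", length(classes), " classes x ",
         markers_per_class, " markers > ", n_genes, " genes")
  }
  if (effect_size <= 0) stop("effect_size must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (baseline_mean < 0) stop("baseline_mean must be >= 0")
  if (!is.null(knockout)) {
    stopifnot(is.list(knockout), knockout$class %in% classes,
              knockout$fraction_of_markers_silenced >= 0,
              knockout$fraction_of_markers_silenced <= 1)
  }
  structure(list(n_genes = n_genes, classes = classes,
                 markers_per_class = markers_per_class,
                 replicates_resource = replicates_resource,
                 replicates_test = replicates_test,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, knockout = knockout,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a paired resource/test synthetic dataset
#'
#' Produces a resource dataset (well-defined reference classes) and a
#' test dataset with the same marker structure, independently sampled
#' noise, and optionally a knockout class whose markers lose (part of)
#' their class effect. Marker gene identifiers are
#' `<class>_marker<1..m>`; background genes are `gene<i>`. The marker
#' assignment is part of the design, not random.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `resource` and `test` ([expression_matrix()]
#'   objects) and `markers`, a named list of marker gene ids per class.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_marker <- length(spec$classes) * spec$markers_per_class
  gene_ids <- c(
    unlist(lapply(spec$classes, function(cl)
      paste0(cl, "_marker", seq_len(spec$markers_per_class)))),
    if (spec$n_genes > n_marker) paste0("gene", seq_len(spec$n_genes - n_marker))
  )
  markers <- stats::setNames(
    lapply(seq_along(spec$classes), function(i)
      gene_ids[(i - 1) * spec$markers_per_class + seq_len(spec$markers_per_class)]),
    spec$classes)

  build <- function(class_per_sample, silence = NULL) {
    p <- length(class_per_sample)
    mu <- matrix(spec$baseline_mean, spec$n_genes, p)
    for (j in seq_len(p)) {
      cl <- sub("\\.KO$", "", class_per_sample[j])
      idx <- match(markers[[cl]], gene_ids)
      eff <- rep(spec$effect_size, length(idx))
      if (!is.null(silence) && endsWith(class_per_sample[j], ".KO")) {
        n_sil <- round(silence$fraction_of_markers_silenced * length(idx))
        if (n_sil > 0) eff[seq_len(n_sil)] <- 0
      }
      mu[idx, j] <- mu[idx, j] + eff
    }
    vals <- mu + matrix(stats::rnorm(spec$n_genes * p, sd = spec$noise_sd),
                        spec$n_genes, p)
    pmax(vals, 0)
  }

  res_classes <- rep(spec$classes, each = spec$replicates_resource)
  res_vals <- build(res_classes)
  resource <- expression_matrix(
    res_vals, gene_ids,
    sample_ids = paste0(res_classes, "_r",
                        sequence(rep(spec$replicates_resource,
                                     length(spec$classes)))),
    sample_class = res_classes)

  test_classes <- rep(spec$classes, each = spec$replicates_test)
  if (!is.null(spec$knockout)) {
    test_classes <- c(test_classes,
                      rep(paste0(spec$knockout$class, ".KO"),
                          spec$replicates_test))
  }
  test_vals <- build(test_classes, silence = spec$knockout)
  test <- expression_matrix(
    test_vals, gene_ids,
    sample_ids = paste0(test_classes, "_t",
                        stats::ave(seq_along(test_classes), test_classes,
                                   FUN = seq_along)),
    sample_class = test_classes)

  list(resource = resource, test = test, markers = markers)
}
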