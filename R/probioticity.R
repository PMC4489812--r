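#' Probioticity score from the reference phenotype variables
#'
#' Condenses the four reference phenotype variables (growth rate, maximal
#' optical density, bile MIC, acid/pepsin yield) into a single probioticity
#' parameter: the columns are scaled, a PCA is fitted, and the PC1 score of
#' each strain is returned with its sign fixed so that the score correlates
#' positively (Spearman) with bile tolerance - higher score, stronger
#' probiotic character. Autoscaling is the default because the four
#' variables carry incommensurate units; Pareto scaling is offered as an
#' alternative.
#'
#' @param pt A phenotype table (see [validate_phenotypes()]); >= 3 strains.
#' @param scaling `"autoscale"` (unit variance) or `"pareto"`.
#' @return A tibble with `strain_id`, `group`, `probioticity`, ordered as
#'   the input, with attributes `pc1_variance_pct` (percent of total variance
#'   explained by PC1) and `pca` (the fitted `nir_pca`).
#' @examples
#' scores <- probioticity_scores(lactobacillus_phenotypes())
#' attr(scores, "pc1_variance_pct")
#' @export
probioticity_scores <- function(pt, scaling = c("autoscale", "pareto")) {
  scaling <- match.arg(scaling)
  pt <- validate_phenotypes(pt)
  if (nrow(pt) < 3) abort("probioticity_scores: need >= 3 strains")
  vars <- c("mu_max", "od_max", "bile_mic", "acid_yield")
  x <- as.matrix(pt[vars])
  sds <- apply(x, 2, sd)
  if (any(sds < 1e-12)) {
    abort("probioticity_scores: a variable has zero variance across strains")
  }
  xs <- switch(scaling,
               autoscale = scale(x),
               pareto = apply_pareto(x, colMeans(x), sds))
  pca <- fit_pca(xs, k = min(nrow(pt) - 1, 4))
  s1 <- pca$scores[, 1]
  if (cor(s1, pt$bile_mic, method = "spearman") < 0) s1 <- -s1
  out <- tibble::tibble(strain_id = pt$strain_id, group = pt$group,
                        probioticity = s1)
  attr(out, "pc1_variance_pct") <- pca$explained_variance_pct[1]
  attr(out, "pca") <- pca
  attr(out, "scaling") <- scaling
  out
}
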