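# Small scenario used where only structure matters, not calibration.
small_scenario <- function(n_clusters = 12, children_per_cluster = 8,
                           n_strata = 3, weight_dispersion = 0.3, ...) {
  mdd_scenario(n_clusters = n_clusters,
               children_per_cluster = children_per_cluster,
               n_strata = n_strata, weight_dispersion = weight_dispersion,
               label = "test", ...)
}

# Build a record data.frame with a given 7-group score per child.
records_with_scores <- function(score7, breastfed,
                                weight = rep(1, length(score7)),
                                cluster = seq_along(score7),
                                stratum = rep("all", length(score7)),
                                age = rep(12L, length(score7))) {
  g <- c("grains", "legumes", "dairy", "flesh", "eggs",
         "vita_fruit_veg", "other_fruit_veg")
  m <- matrix(0L, nrow = length(score7), ncol = 7, dimnames = list(NULL, g))
  for (i in seq_along(score7)) if (score7[i] > 0) m[i, 1:score7[i]] <- 1L
  data.frame(child_id = sprintf("c%03d", seq_along(score7)),
             cluster_id = as.character(cluster),
             stratum_id = as.character(stratum),
             weight = weight, age_months = age,
             breastfed = as.integer(breastfed), m,
             country_label = rep("test", length(score7)),
             stringsAsFactors = FALSE)
}

extdata <- function(f) system.file("extdata", f, package = "mddcompare")
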