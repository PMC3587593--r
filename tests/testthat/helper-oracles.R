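# Independent oracles and fixture builders shared across test files.

# Site likelihood by exhaustive enumeration of the latent occupancy state:
# sum over z in {0, 1} of Bernoulli(z; psi) * prod_j Bernoulli(y_j; z * p_j),
# skipping missing replicates. Deliberately written as the naive double
# loop, independent of the package's vectorised path.
oracle_site_likelihood <- function(y, psi, p) {
  p <- rep_len(p, length(y))
  total <- 0
  for (z in c(0L, 1L)) {
    prior <- if (z == 1L) psi else 1 - psi
    cond <- 1
    for (j in seq_along(y)) {
      if (is.na(y[j])) next
      pj <- z * p[j]
      cond <- cond * if (y[j] == 1) pj else 1 - pj
    }
    total <- total + prior * cond
  }
  total
}

# All-pairs concordance AUC: every (detected, undetected) pair scored
# 1 / 0.5 / 0 for concordant / tied / discordant.
oracle_auc_all_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(conc)
}

# Exhaustive 2-d grid search for the constant model psi(.)p(.) on a small
# dataset with complete histories; exact likelihood evaluated at every
# (psi, p) grid point.
oracle_grid_mle <- function(ndet, J, grid = seq(0.001, 0.999, by = 0.001)) {
  detected <- ndet > 0
  ll <- function(psi, p) {
    sum(ifelse(detected,
      log(psi) + ndet * log(p) + (J - ndet) * log(1 - p),
      log(psi * (1 - p)^J + (1 - psi))
    ))
  }
  vals <- outer(grid, grid, Vectorize(ll))
  best <- arrayInd(which.max(vals), dim(vals))
  c(psi = grid[best[1]], p = grid[best[2]], logL = max(vals))
}

# The fixed 6-site toy survey: histories 110, 000, 100, 000, 011, 000.
toy6_data <- function() {
  occu_data(data.frame(
    site_id = paste0("s", 1:6),
    habitat = "Res1",
    y1 = c(1, 0, 1, 0, 0, 0),
    y2 = c(1, 0, 0, 0, 1, 0),
    y3 = c(0, 0, 0, 0, 1, 0)
  ))
}

# A dataset reproducing a given per-habitat detection pattern: `detected`
# counts (named by habitat) out of `sites` per habitat; detected sites get
# the history 1,0,0. Only detection/non-detection structure is meaningful.
pattern_data <- function(detected = c(
                           Forest = 28, Amenity = 13, Res1 = 12,
                           Res2 = 6, Res3 = 0
                         ),
                         sites = 30) {
  rows <- do.call(rbind, lapply(names(detected), function(h) {
    k <- detected[[h]]
    data.frame(
      site_id = sprintf("%s_%02d", h, seq_len(sites)),
      habitat = h,
      y1 = rep(c(1, 0), c(k, sites - k)),
      y2 = 0, y3 = 0,
      food = 0, forest_area = 0.1,
      stringsAsFactors = FALSE
    )
  }))
  occu_data(rows)
}

# write a dataset-shaped data frame to a temp delimited file
write_temp_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
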