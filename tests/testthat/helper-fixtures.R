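# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

# A complete pipeline run at the default study conditions; reused by the
# interaction, clustering, GO and acceptance tests.
shared_run <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- run_pipeline(sim_config(seed = 42),
                                       k_max = 6, n_restarts = 6)
  }
  .fixture_cache$run
}

# Hand-built CPP table: `strains` is a list of per-strain L values by dose;
# reference cultures are placed symmetrically around `ref_l` so per-dose
# reference means are exact. K/r/auc get distinct reference values so all
# CPP statistics are well defined.
toy_cpp_table <- function(strains, doses = c(0, 2.5, 5, 7.5, 15),
                          ref_l = rep(10, length(doses)),
                          ref_k = rep(100, length(doses)),
                          n_ref = 4, medium = "glycolytic",
                          strain_k = NULL, growth = NULL) {
  rows <- list()
  # symmetric +/- offsets per replicate pair keep per-dose means exact,
  # while the dose-varying wiggle gives the reference series distinct
  # interaction values (so SD(REF_INT) > 0 and z-scores are defined)
  wiggle <- c(0.50, 0.62, 0.43, 0.71, 0.55, 0.66, 0.47, 0.58)
  for (rep_i in seq_len(n_ref)) {
    sgn <- if (rep_i %% 2 == 1) 1 else -1
    scl <- 1 + 0.3 * ((rep_i - 1) %/% 2)
    for (di in seq_along(doses)) {
      delta <- sgn * scl * wiggle[(di - 1) %% length(wiggle) + 1]
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = "REF", medium = medium, dose = doses[di],
        replicate = rep_i, K = ref_k[di] + delta * 2,
        r = 0.3 + delta * 0.01, l = ref_l[di] + delta,
        auc = (ref_k[di] + delta * 2) * 30, rss = 1,
        growth_flag = "growth", stringsAsFactors = FALSE)
    }
  }
  for (sid in names(strains)) {
    lvals <- strains[[sid]]
    kvals <- if (is.null(strain_k)) ref_k else strain_k[[sid]]
    gr <- if (is.null(growth)) rep(TRUE, length(doses)) else growth[[sid]]
    for (di in seq_along(doses)) {
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = sid, medium = medium, dose = doses[di], replicate = 1,
        K = if (gr[di]) kvals[di] else 0, r = if (gr[di]) 0.3 else 0,
        l = if (gr[di]) lvals[di] else NA_real_,
        auc = if (gr[di]) kvals[di] * 30 else 0, rss = 1,
        growth_flag = if (gr[di]) "growth" else "no_growth",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cpp_table", "data.frame")
  out
}

# Exhaustive hypergeometric upper-tail probability by direct summation of
# the counting formula (independent of phyper).
hyper_tail_enum <- function(k, K, N, n) {
  j <- seq(k, min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Adjusted Rand index between two labelings (contingency-table formula).
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
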