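# Drug-gene interaction scoring from CPP tables.
#
# Notation used throughout (per strain, medium and CPP):
#   D_i   dose;  R_i  mean reference CPP at D_i;  Y_i  observed mutant CPP
#   K_i = Y_i - R_i          departure from the reference at D_i
#   K_0  = K_i at D_0        the baseline "shift" of the mutant
#   L_i = K_i - K_0          drug-specific interaction residual (L_0 = 0)
#   L_i = A + B D_i  (OLS);  INT = A + B D_max;  z = (INT - mean REF_INT)/SD REF_INT

.CPPS <- c("L", "K", "r", "AUC")

# melt a cpp_table into (strain, medium, dose, replicate, cpp, value, growth)
.cpp_long <- function(cpps) {
  base <- cpps[c("strain_id", "medium", "dose", "replicate")]
  vals <- list(L = cpps$l, K = cpps$K, r = cpps$r, AUC = cpps$auc)
  out <- do.call(rbind, lapply(.CPPS, function(p) {
    cbind(base, cpp = p, value = vals[[p]],
          growth = cpps$growth_flag == "growth")
  }))
  rownames(out) <- NULL
  out
}

#' Reference-culture statistics for interaction standardization
#'
#' Computes, per medium and CPP, the per-dose mean and sample SD of the
#' reference cultures (`R_i` and its spread), and the null interaction
#' distribution `REF_INT` obtained by running the full interaction
#' procedure on each reference dose-series individually (reference cultures
#' sharing a replicate index across doses form one series). The mean of
#' `REF_INT` is expected to be approximately zero; its SD standardizes the
#' mutant interaction values into z-scores.
#'
#' @param cpps a `cpp_table` from [fit_cpps()], containing reference rows.
#' @param reference_id strain identifier of the reference cultures.
#' @return object of class `"ref_stats"`: list with `doses`, `media`,
#'   `per_dose` (medium, cpp, dose, mean, sd, n), `ref_int` (medium, cpp,
#'   mean, sd, n) and `reference_id`.
#' @export
reference_stats <- function(cpps, reference_id = "REF") {
  ref <- cpps[cpps$strain_id == reference_id, , drop = FALSE]
  if (!nrow(ref)) stop("no reference cultures with strain_id '",
                       reference_id, "'")
  doses <- sort(unique(cpps$dose))
  media <- sort(unique(cpps$medium))
  for (m in media) for (d in doses) {
    n <- sum(ref$medium == m & ref$dose == d)
    if (n < 2L)
      stop("need >= 2 reference cultures per dose; medium '", m,
           "' dose ", d, " has ", n)
  }
  long <- .cpp_long(ref)
  long <- long[long$growth & is.finite(long$value), , drop = FALSE]
  agg <- stats::aggregate(value ~ medium + cpp + dose, data = long,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  per_dose <- data.frame(agg[c("medium", "cpp", "dose")],
                         mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                         n = agg$value[, "n"], stringsAsFactors = FALSE)
  bad <- !is.finite(per_dose$sd) | per_dose$sd <= 0
  if (any(bad))
    stop("reference cultures have zero spread (z-scores undefined) at: ",
         paste(sprintf("%s/%s/dose %g", per_dose$medium[bad],
                       per_dose$cpp[bad], per_dose$dose[bad]),
               collapse = "; "))
  rs <- structure(list(doses = doses, media = media, per_dose = per_dose,
                       ref_int = NULL, reference_id = reference_id),
                  class = "ref_stats")
  # null interaction distribution: score each reference series individually
  yi <- .yi_max_table(cpps, rs)
  recs <- list()
  for (m in media) {
    rm_ <- ref[ref$medium == m, , drop = FALSE]
    for (p in .CPPS) {
      ints <- vapply(split(seq_len(nrow(rm_)), rm_$replicate), function(ii) {
        s <- rm_[ii, , drop = FALSE]
        if (!setequal(s$dose, doses)) return(NA_real_)
        s <- s[match(doses, s$dose), ]
        y <- switch(p, L = s$l, K = s$K, r = s$r, AUC = s$auc)
        .score_series(y, s$growth_flag == "growth", doses,
                      .ref_mean(rs, m, p),
                      yi$max[yi$medium == m][match(doses,
                                                   yi$dose[yi$medium == m])],
                      cpp = p)$INT
      }, 0)
      ints <- ints[is.finite(ints)]
      recs[[length(recs) + 1L]] <- data.frame(
        medium = m, cpp = p, mean = mean(ints), sd = stats::sd(ints),
        n = length(ints), stringsAsFactors = FALSE)
    }
  }
  rs$ref_int <- do.call(rbind, recs)
  bad <- !is.finite(rs$ref_int$sd) | rs$ref_int$sd <= 0
  if (any(bad))
    stop("SD(REF_INT) is zero or undefined for: ",
         paste(sprintf("%s/%s", rs$ref_int$medium[bad],
                       rs$ref_int$cpp[bad]), collapse = "; "))
  rs
}

.ref_mean <- function(rs, medium, cpp) {
  pd <- rs$per_dose
  sel <- pd[pd$medium == medium & pd$cpp == cpp, , drop = FALSE]
  sel$mean[match(rs$doses, sel$dose)]
}

.ref_sd <- function(rs, medium, cpp) {
  pd <- rs$per_dose
  sel <- pd[pd$medium == medium & pd$cpp == cpp, , drop = FALSE]
  sel$sd[match(rs$doses, sel$dose)]
}

#' @export
print.ref_stats <- function(x, ...) {
  cat(sprintf("Reference statistics: %d doses x %d media (reference '%s')\n",
              length(x$doses), length(x$media), x$reference_id))
  cat("REF_INT null distribution:\n")
  print(x$ref_int, row.names = FALSE)
  invisible(x)
}

#' Largest plausible CPP value among healthy cultures at a dose
#'
#' `Y_i max` is the maximum observed CPP value among all cultures at dose
#' `D_i` whose carrying capacity is within 2 SD of the reference mean at
#' that dose (i.e. `K >= mean_ref_K - 2 SD_ref_K`). It is used to impute the
#' unobservable `L` of cultures with no growth curve at a treated dose, and
#' to cap outlying `L` values. When no culture qualifies, the fallback is
#' the reference mean of the CPP at that dose plus 2 reference SDs.
#'
#' @param cpps a `cpp_table`.
#' @param refstats a [reference_stats()] object.
#' @param medium,dose stratum.
#' @param cpp CPP name (default `"L"`).
#' @return a single numeric value.
#' @export
compute_yi_max <- function(cpps, refstats, medium, dose, cpp = "L") {
  pd <- refstats$per_dose
  kref <- pd[pd$medium == medium & pd$cpp == "K" & pd$dose == dose, ]
  vref <- pd[pd$medium == medium & pd$cpp == cpp & pd$dose == dose, ]
  if (!nrow(kref) || !nrow(vref))
    stop("no reference statistics for medium '", medium, "' dose ", dose)
  sel <- cpps$medium == medium & cpps$dose == dose &
    cpps$growth_flag == "growth" & cpps$K >= kref$mean - 2 * kref$sd
  v <- switch(cpp, L = cpps$l, K = cpps$K, r = cpps$r, AUC = cpps$auc)[sel]
  v <- v[is.finite(v)]
  if (!length(v)) return(vref$mean + 2 * vref$sd)
  max(v)
}

.yi_max_table <- function(cpps, refstats, cpp = "L") {
  grid <- expand.grid(medium = refstats$media, dose = refstats$doses,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$max <- mapply(function(m, d) compute_yi_max(cpps, refstats, m, d, cpp),
                     grid$medium, grid$dose)
  grid
}

# Core of the scoring procedure for one (strain, medium, CPP) dose series.
# y: observed CPP per dose; growth: growth-curve flag per dose.
.score_series <- function(y, growth, doses, ref_mean, yi_max, cpp,
                          cap_outliers = TRUE) {
  if (cpp == "L") {
    y[!growth] <- yi_max[!growth]
    if (cap_outliers) {
      hi <- growth & is.finite(y) & y > yi_max
      y[hi] <- yi_max[hi]
    }
  } else {
    y[!growth] <- 0
  }
  ki <- y - ref_mean
  k0 <- ki[1]
  li <- ki - k0
  dbar <- mean(doses); lbar <- mean(li)
  B <- sum((doses - dbar) * (li - lbar)) / sum((doses - dbar)^2)
  A <- lbar - B * dbar
  list(shift = k0, A = A, B = B, INT = A + B * max(doses))
}

#' Score drug-gene interaction for every strain
#'
#' Runs the full interaction procedure for each (strain, medium): impute
#' missing/no-growth values (`Y_i = 0` for K, r and AUC; `Y_i max` for L,
#' which is also used to cap outlying L values), subtract the per-dose
#' reference mean to get `K_i`, subtract the dose-0 shift `K_0` to get
#' `L_i`, fit `L_i = A + B D_i` by ordinary least squares over all doses
#' (dose 0 included, intercept estimated), evaluate `INT = A + B D_max`,
#' and standardize against the reference null:
#' `z = (INT - mean(REF_INT)) / SD(REF_INT)`.
#'
#' A strain with no growth curve at dose 0 in a medium has no defined
#' interaction there: its z-scores are `NA`, `no_growth_d0` is set, and
#' display exports substitute the sentinel value 0.0001 (see
#' [cluster_heatmap_matrix()]).
#'
#' @param cpps a `cpp_table` from [fit_cpps()].
#' @param refstats a [reference_stats()] object.
#' @param threshold z threshold for enhancer/suppressor calls.
#' @param cap_outliers cap observed L above `Y_i max` (the default mirrors
#'   the imputation rule's scope: L only).
#' @return data.frame of class `c("interaction_table", "data.frame")`, one
#'   row per (strain, medium): shift, A, B, INT and z for L and K, z for r
#'   and AUC, the combined `call`, and `no_growth_d0`.
#' @seealso [classify_interaction()], [classify_warburg()]
#' @export
score_interactions <- function(cpps, refstats, threshold = 2,
                               cap_outliers = TRUE) {
  doses <- refstats$doses
  yi <- .yi_max_table(cpps, refstats)
  mut <- cpps[cpps$strain_id != refstats$reference_id, , drop = FALSE]
  out <- list()
  for (m in refstats$media) {
    mm <- mut[mut$medium == m, , drop = FALSE]
    if (!nrow(mm)) next
    yim <- yi$max[yi$medium == m][match(doses, yi$dose[yi$medium == m])]
    rint <- refstats$ref_int[refstats$ref_int$medium == m, ]
    for (sid in unique(mm$strain_id)) {
      s <- mm[mm$strain_id == sid, , drop = FALSE]
      # average replicates within dose; growth if any replicate grew
      rec <- list(strain_id = sid, medium = m)
      growth <- vapply(doses, function(d)
        any(s$growth_flag[s$dose == d] == "growth"), TRUE)
      if (any(!vapply(doses, function(d) any(s$dose == d), TRUE))) {
        warning("strain ", sid, " in ", m, " is missing doses; skipped")
        next
      }
      if (!growth[1]) {  # no growth untreated: interaction undefined
        rec <- c(rec, as.list(stats::setNames(
          rep(NA_real_, 14),
          c("shift_L", "a_L", "b_L", "int_L", "z_L",
            "shift_K", "a_K", "b_K", "int_K", "z_K",
            "int_r", "z_r", "int_AUC", "z_AUC"))),
          list(no_growth_d0 = TRUE, call = NA_character_))
        out[[length(out) + 1L]] <- as.data.frame(rec, stringsAsFactors = FALSE)
        next
      }
      zs <- list()
      for (p in .CPPS) {
        v <- switch(p, L = s$l, K = s$K, r = s$r, AUC = s$auc)
        g <- s$growth_flag == "growth"
        y <- vapply(doses, function(d) {
          vv <- v[s$dose == d & g]
          if (length(vv)) mean(vv) else NA_real_
        }, 0)
        sc <- .score_series(y, growth, doses, .ref_mean(refstats, m, p),
                            yim, cpp = p, cap_outliers = cap_outliers)
        ri <- rint[rint$cpp == p, ]
        zs[[p]] <- c(sc, z = (sc$INT - ri$mean) / ri$sd)
      }
      rec <- c(rec, list(
        shift_L = zs$L$shift, a_L = zs$L$A, b_L = zs$L$B,
        int_L = zs$L$INT, z_L = zs$L$z,
        shift_K = zs$K$shift, a_K = zs$K$A, b_K = zs$K$B,
        int_K = zs$K$INT, z_K = zs$K$z,
        int_r = zs$r$INT, z_r = zs$r$z,
        int_AUC = zs$AUC$INT, z_AUC = zs$AUC$z,
        no_growth_d0 = FALSE,
        call = classify_interaction(zs$L$z, zs$K$z, threshold)))
      out[[length(out) + 1L]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  class(res) <- c("interaction_table", "data.frame")
  res
}

#' Classify a strain from its L and K interaction z-scores
#'
#' Deletion enhancement (the mutant is hurt more by the drug than the
#' reference) is called when `z_L >= threshold` or `z_K <= -threshold`;
#' deletion suppression when `z_L <= -threshold` or `z_K >= threshold`.
#' A strain satisfying rules in both directions (e.g. `z_L` and `z_K` both
#' strongly positive) is reported as `"conflict"`.
#'
#' @param z_L,z_K numeric vectors of z-scores (recycled to common length).
#' @param threshold positive z cutoff (default 2).
#' @return character vector: `"enhancer"`, `"suppressor"`, `"conflict"` or
#'   `"none"` (`NA` where both inputs are `NA`).
#' @export
classify_interaction <- function(z_L, z_K, threshold = 2) {
  if (threshold <= 0) stop("threshold must be > 0")
  n <- max(length(z_L), length(z_K))
  z_L <- rep_len(z_L, n); z_K <- rep_len(z_K, n)
  enh <- (!is.na(z_L) & z_L >= threshold) | (!is.na(z_K) & z_K <= -threshold)
  sup <- (!is.na(z_L) & z_L <= -threshold) | (!is.na(z_K) & z_K >= threshold)
  out <- rep("none", n)
  out[enh & !sup] <- "enhancer"
  out[sup & !enh] <- "suppressor"
  out[enh & sup] <- "conflict"
  out[is.na(z_L) & is.na(z_K)] <- NA_character_
  out
}

#' Classify Warburg dependence of interaction calls across media
#'
#' Compares a strain's enhancer/suppressor call between the respiratory and
#' glycolytic context: non-specific (`NS`) when the same call holds in both
#' media, respiratory-specific (`R`) or glycolysis-specific (`G`) when it
#' holds in only one. Opposite calls in the two media are reported as
#' `"conflict"`; a missing or `none` call in both media gives `"none"`.
#'
#' @param scores an `interaction_table` covering both media.
#' @param respiratory,glycolytic medium labels.
#' @return data.frame `strain_id`, `call_respiratory`, `call_glycolytic`,
#'   `warburg` (e.g. `"NS-Enh"`, `"R-Enh"`, `"G-Sup"`, `"none"`,
#'   `"conflict"`).
#' @export
classify_warburg <- function(scores, respiratory = "respiratory",
                             glycolytic = "glycolytic") {
  need <- c(respiratory, glycolytic)
  if (!all(need %in% scores$medium))
    stop("scores must cover media: ", paste(need, collapse = ", "))
  r <- scores[scores$medium == respiratory, c("strain_id", "call")]
  g <- scores[scores$medium == glycolytic, c("strain_id", "call")]
  mg <- merge(r, g, by = "strain_id", suffixes = c("_r", "_g"))
  one <- function(cr, cg) {
    cr <- ifelse(is.na(cr) | cr == "conflict", "none", cr)
    cg <- ifelse(is.na(cg) | cg == "conflict", "none", cg)
    if (cr == "none" && cg == "none") return("none")
    if (cr != "none" && cg != "none" && cr != cg) return("conflict")
    tag <- c(enhancer = "Enh", suppressor = "Sup")
    if (cr == cg) return(paste0("NS-", tag[[cr]]))
    if (cr != "none") return(paste0("R-", tag[[cr]]))
    paste0("G-", tag[[cg]])
  }
  data.frame(strain_id = mg$strain_id,
             call_respiratory = mg$call_r, call_glycolytic = mg$call_g,
             warburg = mapply(one, mg$call_r, mg$call_g, USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Compare interaction scores between two runs
#'
#' Retest concordance: Pearson and Spearman correlation of L z-scores over
#' the shared strain set, per medium, as used to validate a re-run of the
#' screen against the original.
#'
#' @param scores1,scores2 `interaction_table`s sharing strains.
#' @return data.frame `medium`, `n`, `pearson`, `spearman`.
#' @export
compare_runs <- function(scores1, scores2) {
  mg <- merge(scores1[c("strain_id", "medium", "z_L")],
              scores2[c("strain_id", "medium", "z_L")],
              by = c("strain_id", "medium"), suffixes = c("_1", "_2"))
  mg <- mg[is.finite(mg$z_L_1) & is.finite(mg$z_L_2), , drop = FALSE]
  if (!nrow(mg)) stop("no shared scored strains between runs")
  do.call(rbind, lapply(split(mg, mg$medium), function(s) {
    data.frame(medium = s$medium[1], n = nrow(s),
               pearson = stats::cor(s$z_L_1, s$z_L_2),
               spearman = stats::cor(s$z_L_1, s$z_L_2, method = "spearman"),
               stringsAsFactors = FALSE)
  }))
}
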