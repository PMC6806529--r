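# Expression-sensitivity association in cell-line panels and homology-based
# matching to yeast interaction evidence.

#' Differential expression versus drug sensitivity
#'
#' For each gene, regresses standardized expression on standardized drug
#' sensitivity by ordinary least squares; the standardized coefficient then
#' equals the Pearson correlation, with a two-sided p-value from the t
#' statistic on `n - 2` degrees of freedom. A positive coefficient means
#' higher expression in more sensitive lines. Run either on all lines
#' pooled (`tissue = NULL` or `stratify = FALSE`, stratum `"all"`) or
#' additionally within each tissue stratum.
#'
#' @param expression genes x lines numeric matrix.
#' @param sensitivity named numeric vector of per-line sensitivity (higher
#'   = more sensitive); names must match the expression columns.
#' @param tissue optional named character vector of tissue labels.
#' @param stratify if `TRUE` and `tissue` given, also analyze each stratum
#'   with at least `min_lines` lines.
#' @param min_lines minimum lines per stratum.
#' @return data.frame `gene`, `tissue`, `coefficient`, `p`, `n`,
#'   `skipped` (`TRUE` for zero-variance genes, which get `NA` results).
#' @export
differential_expression <- function(expression, sensitivity, tissue = NULL,
                                    stratify = FALSE, min_lines = 3) {
  lines <- intersect(colnames(expression), names(sensitivity))
  if (length(lines) < min_lines)
    stop("need at least ", min_lines, " shared cell lines")
  strata <- list(all = lines)
  if (!is.null(tissue) && stratify) {
    for (tt in unique(tissue[lines])) {
      memb <- lines[tissue[lines] == tt]
      if (length(memb) >= min_lines) strata[[tt]] <- memb
    }
  }
  out <- do.call(rbind, lapply(names(strata), function(st) {
    cols <- strata[[st]]
    x <- expression[, cols, drop = FALSE]
    s <- sensitivity[cols]
    n <- length(cols)
    sdx <- apply(x, 1, stats::sd)
    ok <- is.finite(sdx) & sdx > 0 & stats::sd(s) > 0
    r <- rep(NA_real_, nrow(x))
    xs <- sweep(sweep(x[ok, , drop = FALSE], 1, rowMeans(x[ok, , drop = FALSE])),
                1, sdx[ok], "/")
    ss <- as.vector(scale(s))
    r[ok] <- as.vector(xs %*% ss) / (n - 1)
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    data.frame(gene = rownames(x), tissue = st, coefficient = r, p = p,
               n = n, skipped = !ok, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Call UES/OES genes from differential-expression results
#'
#' UES (under-expressed in sensitive lines): `p < alpha` and negative
#' coefficient. OES (over-expressed in sensitive lines): `p < alpha` and
#' positive coefficient.
#'
#' @param de a [differential_expression()] table.
#' @param alpha nominal significance level (default 0.05, uncorrected).
#' @return `de` with an added `direction` column (`"UES"`, `"OES"`,
#'   `"none"`).
#' @export
call_ues_oes <- function(de, alpha = 0.05) {
  sig <- !is.na(de$p) & de$p < alpha & !is.na(de$coefficient)
  de$direction <- "none"
  de$direction[sig & de$coefficient < 0] <- "UES"
  de$direction[sig & de$coefficient > 0] <- "OES"
  de
}

#' Predict human modifiers of drug response from yeast interaction evidence
#'
#' Joins yeast deletion enhancers to UES human homologs and yeast deletion
#' suppressors to OES homologs: if knocking out the yeast gene makes cells
#' more sensitive to the drug (enhancer), low expression of its human
#' homolog in sensitive tumor lines is consistent with a causal role, and
#' conversely for suppressors. Direction mismatches are never emitted.
#'
#' @param scores an `interaction_table` (both media) for the yeast side.
#' @param homology data.frame `yeast_gene`, `human_gene`, `homology_class`.
#' @param calls_by_dataset named list of [call_ues_oes()] tables (one per
#'   cell-line panel); only rows of the `"all"` tissue stratum are used
#'   unless `tissue` is given.
#' @param tissue tissue stratum to read from the call tables.
#' @param respiratory,glycolytic medium labels for Warburg annotation.
#' @return data.frame of class `c("prediction_table", "data.frame")`:
#'   `human_gene`, `direction`, `yeast_gene`, `homology_class`,
#'   `media_called` (comma-joined), `warburg`, `n_datasets` (panels
#'   agreeing on the direction), `datasets`, `priority` (`TRUE` when
#'   supported by >= 2 panels and called in both media).
#' @export
match_predictions <- function(scores, homology, calls_by_dataset,
                              tissue = "all",
                              respiratory = "respiratory",
                              glycolytic = "glycolytic") {
  wb <- classify_warburg(scores, respiratory, glycolytic)
  calls <- lapply(calls_by_dataset, function(d)
    d[d$tissue == tissue & d$direction != "none", , drop = FALSE])
  # per-strain media where each direction was called
  media_of <- function(sid, want) {
    s <- scores[scores$strain_id == sid & !is.na(scores$call) &
                  scores$call == want, "medium"]
    sort(unique(s))
  }
  out <- list()
  for (i in seq_len(nrow(homology))) {
    yg <- homology$yeast_gene[i]; hg <- homology$human_gene[i]
    for (pair in list(c("enhancer", "UES"), c("suppressor", "OES"))) {
      med <- media_of(yg, pair[1])
      if (!length(med)) next
      hit <- vapply(calls, function(d)
        any(d$gene == hg & d$direction == pair[2]), TRUE)
      if (!any(hit)) next
      out[[length(out) + 1L]] <- data.frame(
        human_gene = hg, direction = pair[2], yeast_gene = yg,
        homology_class = homology$homology_class[i],
        media_called = paste(med, collapse = ","),
        warburg = wb$warburg[match(yg, wb$strain_id)],
        n_datasets = sum(hit),
        datasets = paste(names(calls)[hit], collapse = ","),
        tissue = tissue,
        priority = sum(hit) >= 2 &&
          all(c(respiratory, glycolytic) %in% med),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(human_gene = character(0), direction = character(0),
               yeast_gene = character(0), homology_class = character(0),
               media_called = character(0), warburg = character(0),
               n_datasets = integer(0), datasets = character(0),
               tissue = character(0), priority = logical(0))
  rownames(res) <- NULL
  class(res) <- c("prediction_table", "data.frame")
  res
}
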