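# GO-based functional analysis: hypergeometric enrichment of clusters and
# term averaging (GTA) of interaction scores.

#' Read a GO annotation table
#'
#' Accepts either a simple two-column tab-separated file (`term_id`, `gene`)
#' or a GAF 2.x association file (comment lines starting with `!`; column 3
#' is the object symbol, column 5 the GO id).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gaf"`.
#' @return data.frame `term_id`, `gene` (unique pairs).
#' @export
read_go_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("term_id", "gene") %in% names(x))) {
      x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
      names(x)[1:2] <- c("term_id", "gene")
    }
    out <- x[c("term_id", "gene")]
  } else {
    x <- utils::read.delim(path, header = FALSE, comment.char = "!",
                           stringsAsFactors = FALSE)
    out <- data.frame(term_id = x[[5]], gene = x[[3]],
                      stringsAsFactors = FALSE)
  }
  unique(out)
}

#' Parse is_a edges from an OBO 1.4 ontology file
#'
#' Minimal stanza parser extracting `id:` and `is_a:` lines from `[Term]`
#' blocks, for optional ancestor propagation of annotations.
#'
#' @param path OBO file path.
#' @return data.frame `term_id`, `parent_id`.
#' @export
read_obo_isa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cur <- NA_character_
  in_term <- FALSE
  from <- character(0); to <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "[")) { in_term <- identical(ln, "[Term]"); cur <- NA }
    else if (in_term && startsWith(ln, "id: ")) cur <- sub("^id: ", "", ln)
    else if (in_term && startsWith(ln, "is_a: ") && !is.na(cur)) {
      parent <- sub("^is_a: *([^ !]+).*$", "\\1", ln)
      from <- c(from, cur); to <- c(to, parent)
    }
  }
  data.frame(term_id = from, parent_id = to, stringsAsFactors = FALSE)
}

#' Propagate annotations to ancestor terms
#'
#' Each gene annotated to a term is also annotated to every ancestor along
#' `is_a` edges (transitive closure), matching the convention of curated
#' propagated association downloads.
#'
#' @param annotations data.frame `term_id`, `gene`.
#' @param isa data.frame `term_id`, `parent_id` from [read_obo_isa()].
#' @return data.frame `term_id`, `gene` including propagated pairs.
#' @export
propagate_annotations <- function(annotations, isa) {
  out <- unique(annotations[c("term_id", "gene")])
  repeat {
    up <- merge(out, isa, by = "term_id")
    if (!nrow(up)) break
    up <- unique(data.frame(term_id = up$parent_id, gene = up$gene,
                            stringsAsFactors = FALSE))
    new <- up[!(paste(up$term_id, up$gene) %in%
                  paste(out$term_id, out$gene)), , drop = FALSE]
    if (!nrow(new)) break
    out <- rbind(out, new)
  }
  rownames(out) <- NULL
  out
}

#' Hypergeometric GO-term enrichment of a gene cluster
#'
#' For each term, tests whether the cluster contains more term members than
#' expected from the background universe, by the one-sided hypergeometric
#' upper tail: with `N` universe genes of which `K` carry the term, and a
#' cluster of `n` genes containing `k` term members,
#' `p = P(X >= k)`, `X ~ Hypergeometric(N, K, n)`. Bonferroni-adjusted
#' p-values (by the number of terms tested) are reported alongside.
#'
#' @param cluster_genes character vector of cluster members.
#' @param annotations data.frame `term_id`, `gene`.
#' @param universe background gene universe (all scored genes). Annotations
#'   outside the universe are dropped; terms with no universe member are
#'   skipped.
#' @return data.frame `term_id`, `k`, `n`, `K`, `N`, `p`, `p_adj`, sorted
#'   by `p`.
#' @export
enrich_terms <- function(cluster_genes, annotations, universe) {
  universe <- unique(universe)
  cluster_genes <- intersect(unique(cluster_genes), universe)
  ann <- annotations[annotations$gene %in% universe, , drop = FALSE]
  terms <- split(unique(ann)$gene, unique(ann)$term_id)
  terms <- terms[lengths(terms) > 0]
  N <- length(universe); n <- length(cluster_genes)
  out <- do.call(rbind, lapply(names(terms), function(tid) {
    members <- terms[[tid]]
    K <- length(members)
    k <- length(intersect(cluster_genes, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(term_id = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p = numeric(0), p_adj = numeric(0)))
  out$p_adj <- pmin(1, out$p * nrow(out))
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' GO term average (GTA) of interaction values
#'
#' The GTA of a term is the mean of its member genes' interaction values;
#' `gtaSD` is their sample SD (n - 1 denominator), and the GTA score is
#' `|GTA value| - gtaSD`. A term is significant when `|GTA value| >
#' value_threshold` and the GTA score exceeds `score_threshold` (both
#' default 2): a strong average interaction that is not explained away by
#' within-term spread.
#'
#' @param values numeric interaction values of the term's member genes.
#' @param value_threshold,score_threshold the two-stage filter cutoffs.
#' @return one-row data.frame: `n`, `gta_value`, `gta_sd`, `gta_score`,
#'   `significant`. With fewer than 2 values the SD and score are `NA` and
#'   the term is never significant.
#' @examples
#' compute_gta(c(-13.9, -10.5))  # mean -12.2, SD 2.4
#' @export
compute_gta <- function(values, value_threshold = 2, score_threshold = 2) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) {
    return(data.frame(n = n, gta_value = if (n) mean(values) else NA_real_,
                      gta_sd = NA_real_, gta_score = NA_real_,
                      significant = FALSE))
  }
  v <- mean(values)
  s <- stats::sd(values)
  score <- abs(v) - s
  data.frame(n = n, gta_value = v, gta_sd = s, gta_score = score,
             significant = abs(v) > value_threshold & score > score_threshold)
}

#' GTA scan over all GO terms
#'
#' Computes [compute_gta()] for every term against the interaction z-scores
#' of one medium and CPP (the L scores by default), dropping annotation
#' genes absent from the scored set. Optionally cross-references an
#' enrichment table to mark terms that were also found by cluster
#' enrichment.
#'
#' @param scores an `interaction_table`.
#' @param annotations data.frame `term_id`, `gene`.
#' @param medium medium to scan.
#' @param cpp `"L"` (default) or `"K"`.
#' @param value_threshold,score_threshold filter cutoffs (see
#'   [compute_gta()]).
#' @param enrichment optional data.frame with columns `term_id` (and
#'   optionally `cluster`) of enrichment hits to cross-reference.
#' @return data.frame, one row per term with >= 2 scored members:
#'   `term_id`, `medium`, `cpp`, `n`, `gta_value`, `gta_sd`, `gta_score`,
#'   `significant`, `genes` (comma-collapsed), and `remc_related` if
#'   `enrichment` was supplied.
#' @export
gta_scan <- function(scores, annotations, medium, cpp = "L",
                     value_threshold = 2, score_threshold = 2,
                     enrichment = NULL) {
  zcol <- paste0("z_", cpp)
  if (!zcol %in% names(scores)) stop("no column ", zcol, " in scores")
  s <- scores[scores$medium == medium, c("strain_id", zcol)]
  z <- stats::setNames(s[[zcol]], s$strain_id)
  z <- z[is.finite(z)]
  terms <- split(annotations$gene, annotations$term_id)
  out <- do.call(rbind, lapply(names(terms), function(tid) {
    members <- intersect(unique(terms[[tid]]), names(z))
    if (length(members) < 2) return(NULL)
    g <- compute_gta(z[members], value_threshold, score_threshold)
    cbind(data.frame(term_id = tid, medium = medium, cpp = cpp,
                     stringsAsFactors = FALSE),
          g, genes = paste(sort(members), collapse = ","))
  }))
  if (is.null(out))
    return(data.frame(term_id = character(0), medium = character(0),
                      cpp = character(0), n = integer(0),
                      gta_value = numeric(0), gta_sd = numeric(0),
                      gta_score = numeric(0), significant = logical(0),
                      genes = character(0)))
  if (!is.null(enrichment))
    out$remc_related <- out$term_id %in% enrichment$term_id
  out <- out[order(-abs(out$gta_value)), ]
  rownames(out) <- NULL
  out
}

#' Heatmap matrix for a single GO term
#'
#' The full interaction profiles (4 z-score features plus shifts) of a
#' term's scored members, ordered as in [cluster_heatmap_matrix()].
#'
#' @param term_id the GO term.
#' @param annotations data.frame `term_id`, `gene`.
#' @param pm a [select_profiles()] matrix built with `threshold = 0` if all
#'   scored genes should be available, or the analysis matrix for selected
#'   genes only.
#' @return ordered numeric matrix of member profiles.
#' @export
term_heatmap_matrix <- function(term_id, annotations, pm) {
  members <- unique(annotations$gene[annotations$term_id == term_id])
  members <- intersect(members, rownames(pm))
  if (!length(members))
    stop("term ", term_id, " has no members among the profiled genes")
  cluster_heatmap_matrix(pm, members)
}
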