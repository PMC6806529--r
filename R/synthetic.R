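#' Simulate culture intensity time series with planted drug-gene interactions
#'
#' Generates the image-intensity time series the pipeline starts from, for a
#' mutant library plus replicate reference cultures, under the logistic
#' growth family the fitting stage assumes. Each culture's curve is
#' `G(t) = K / (1 + exp(-r (t - l)))` plus truncated Gaussian noise, where
#' for a mutant strain at dose `D`
#' \itemize{
#'   \item `l = l_ref + dose_slope_l * D + shift_l + slope_l * D`
#'   \item `K = K_ref + dose_slope_k * D + shift_k + slope_k * D`
#' }
#' The first two terms are the reference dose response (shared by all
#' cultures), the `shift_*` terms are strain-specific baseline offsets
#' present already at dose 0, and the `slope_*` terms are the planted
#' dose-by-gene interactions that downstream scoring should recover.
#' Reference cultures have shift and slope 0. Petite-like strains produce
#' flat baseline noise in respiratory medium at every dose.
#'
#' @param config a [sim_config()] object.
#' @param truth optional ground-truth table from a previous
#'   `simulate_phenomics()` run: when supplied, the same strains, shifts
#'   and interaction slopes are reused and only fresh culture-level noise
#'   is drawn, emulating an independent retest of the same library (the
#'   validation design; see [compare_runs()]).
#' @return a list of class `"phenomic_sim"` with elements
#'   \describe{
#'     \item{timeseries}{long data.frame: `strain_id`, `medium`, `dose`,
#'       `replicate`, `time_h`, `intensity`. Reference cultures carry
#'       `strain_id == "REF"` and are distinguished by `replicate`.}
#'     \item{truth}{per (strain, medium) ground truth: planted class,
#'       baseline shifts, interaction slopes, no-growth flag, and the
#'       planted L displacement at the maximum dose (`effect_l_dmax`).}
#'   }
#' @export
simulate_phenomics <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_strains
  doses <- config$doses
  dmax <- max(doses)
  times <- seq(0, config$horizon, by = config$sampling_interval)

  if (is.null(truth)) truth <- .build_truth(config)
  strain_id <- unique(truth$strain_id)

  n_ref_series <- max(2L, round(config$n_reference_cultures / length(doses)))

  rows <- vector("list", 2L * length(config$media))
  ri <- 0L
  for (m in config$media) {
    p <- config$reference[[m]]
    tm <- truth[truth$medium == m, , drop = FALSE]
    # mutant cultures: grid of strain x dose x replicate
    grid <- expand.grid(strain_id = strain_id, dose = doses,
                        replicate = seq_len(config$replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    j <- match(grid$strain_id, tm$strain_id)
    l_mu <- p["l"] + config$dose_slope_l[[m]] * grid$dose +
      tm$shift_l[j] + tm$slope_l[j] * grid$dose
    k_mu <- p["K"] + config$dose_slope_k[[m]] * grid$dose +
      tm$shift_k[j] + tm$slope_k[j] * grid$dose
    grid$no_growth <- tm$no_growth[j]
    ri <- ri + 1L
    rows[[ri]] <- .culture_block(grid, m, l_mu, k_mu, p["r"], times, config)
    # reference cultures: one series per replicate index, slope and shift 0
    rgrid <- expand.grid(strain_id = "REF", dose = doses,
                         replicate = seq_len(n_ref_series),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rgrid$no_growth <- FALSE
    l_mu <- p["l"] + config$dose_slope_l[[m]] * rgrid$dose
    k_mu <- p["K"] + config$dose_slope_k[[m]] * rgrid$dose
    ri <- ri + 1L
    rows[[ri]] <- .culture_block(rgrid, m, l_mu, k_mu, p["r"], times, config)
  }
  ts <- do.call(rbind, rows)
  rownames(ts) <- NULL
  structure(list(timeseries = ts, truth = truth, config = config),
            class = "phenomic_sim")
}

# draw the per-(strain, medium) ground-truth table for a configuration
.build_truth <- function(config) {
  n <- config$n_strains
  dmax <- max(config$doses)
  strain_id <- sprintf("YKO%04d", seq_len(n))
  n_enh <- round(config$fraction_enhancer * n)
  n_sup <- round(config$fraction_suppressor * n)
  n_pet <- round(config$fraction_no_growth * n)
  class_vec <- rep("neutral", n)
  idx <- sample.int(n, n_enh + n_sup + n_pet)
  class_vec[idx[seq_len(n_enh)]] <- "enhancer"
  if (n_sup) class_vec[idx[n_enh + seq_len(n_sup)]] <- "suppressor"
  if (n_pet) class_vec[idx[n_enh + n_sup + seq_len(n_pet)]] <- "no_growth"
  # which media a planted effect acts in, to create Warburg-specific classes;
  # cycled (not sampled) so every class is guaranteed represented
  scope <- rep("both", n)
  if (length(config$media) >= 2L) {
    pat <- c("both", config$media[length(config$media)], "both",
             config$media[1])
    for (cls in c("enhancer", "suppressor")) {
      w <- which(class_vec == cls)
      scope[w] <- rep_len(pat, length(w))
    }
  } else {
    scope[class_vec %in% c("enhancer", "suppressor")] <- config$media[1]
  }

  truth <- expand.grid(strain_id = strain_id, medium = config$media,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth <- truth[order(truth$strain_id, truth$medium), , drop = FALSE]
  i <- match(truth$strain_id, strain_id)
  truth$class <- class_vec[i]
  truth$scope <- scope[i]
  truth$shift_l <- stats::rnorm(nrow(truth), 0, config$shift_sd_h)
  refK <- vapply(truth$medium, function(m) config$reference[[m]]["K"], 0)
  truth$shift_k <- stats::rnorm(nrow(truth), 0, config$shift_sd_frac_k * refK)
  # planted effect magnitude (hours of L displacement at max dose), per strain
  eff <- abs(stats::rnorm(n, config$effect_l_h, config$effect_sd_h))
  eff <- pmax(eff, 0.5)
  sgn <- ifelse(class_vec == "enhancer", 1, ifelse(class_vec == "suppressor", -1, 0))
  active <- sgn[i] != 0 & (truth$scope == "both" | truth$scope == truth$medium)
  truth$effect_l_dmax <- ifelse(active, sgn[i] * eff[i], 0)
  truth$slope_l <- truth$effect_l_dmax / dmax
  truth$slope_k <- -sign(truth$effect_l_dmax) * config$effect_k_frac * refK / dmax
  truth$no_growth <- class_vec[i] == "no_growth" & truth$medium == "respiratory"
  # petite strains behave neutrally where they do grow
  truth$shift_l[truth$no_growth] <- 0
  truth$shift_k[truth$no_growth] <- 0
  rownames(truth) <- NULL
  truth
}

# expand one block of cultures into noisy logistic time series rows
.culture_block <- function(grid, medium, l_mu, k_mu, r_ref, times, config) {
  nc <- nrow(grid)
  nt <- length(times)
  l <- l_mu + stats::rnorm(nc, 0, config$culture_sd_h)
  K <- pmax(k_mu + stats::rnorm(nc, 0, config$culture_sd_k), 1)
  r <- rep(r_ref, nc)
  tt <- rep(times, nc)
  Kv <- rep(K, each = nt); rv <- rep(r, each = nt); lv <- rep(l, each = nt)
  g <- Kv / (1 + exp(-rv * (tt - lv)))
  ng <- rep(grid$no_growth, each = nt)
  g[ng] <- 2  # residual background intensity of a non-growing spot
  y <- g + stats::rnorm(nc * nt, 0, config$noise_sd)
  data.frame(strain_id = rep(grid$strain_id, each = nt),
             medium = medium,
             dose = rep(grid$dose, each = nt),
             replicate = rep(grid$replicate, each = nt),
             time_h = tt,
             intensity = pmax(y, 0),
             stringsAsFactors = FALSE)
}

#' Simulate a GO annotation table with planted coherent modules
#'
#' Draws random gene sets ("terms") over the strain universe, plus a number
#' of planted terms whose members all share the same planted interaction
#' sign, so term-averaging and enrichment stages have known positives.
#'
#' @param truth the `truth` table from [simulate_phenomics()].
#' @param n_terms total number of terms.
#' @param size_range integer range of random term sizes (minimum 2: a
#'   single-gene term has no defined SD and is rejected).
#' @param n_planted number of planted terms.
#' @param planted_size genes per planted term.
#' @param planted_class planted member class, `"enhancer"` or `"suppressor"`.
#' @param seed integer seed.
#' @return data.frame `term_id`, `gene`, with attributes `planted_terms`
#'   (character vector) and `term_names`.
#' @export
simulate_go <- function(truth, n_terms = 40, size_range = c(3, 10),
                        n_planted = 3, planted_size = 4,
                        planted_class = "enhancer", seed = 1) {
  if (min(size_range) < 2 || planted_size < 2)
    stop("term sizes below 2 are not allowed: the term SD is undefined")
  set.seed(seed)
  universe <- unique(truth$strain_id)
  # planted members: strains carrying the planted class in every medium;
  # planted terms may share genes when the pool is small, as real GO terms do
  cand <- unique(truth$strain_id[truth$class == planted_class &
                                   truth$scope == "both"])
  if (length(cand) < planted_size)
    stop("not enough '", planted_class,
         "' strains with effects in both media to plant a term of size ",
         planted_size)
  out <- vector("list", n_terms)
  planted_ids <- character(0)
  for (t in seq_len(n_terms)) {
    id <- sprintf("GO:%07d", t)
    if (t <= n_planted) {
      genes <- sample(cand, planted_size)
      planted_ids <- c(planted_ids, id)
    } else {
      sz <- sample(seq(min(size_range), max(size_range)), 1)
      genes <- sample(universe, sz)
    }
    out[[t]] <- data.frame(term_id = id, gene = genes,
                           stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, out)
  attr(ann, "planted_terms") <- planted_ids
  attr(ann, "term_names") <- stats::setNames(
    ifelse(seq_len(n_terms) <= n_planted,
           sprintf("planted %s module %d", planted_class, seq_len(n_terms)),
           sprintf("random term %d", seq_len(n_terms))),
    sprintf("GO:%07d", seq_len(n_terms)))
  ann
}

#' Simulate a cell-line pharmacogenomic dataset with planted UES/OES genes
#'
#' Emulates a cancer cell-line panel with an expression matrix, a continuous
#' drug-sensitivity score per line (AAC-like: higher means more sensitive),
#' and tissue labels. Planted UES genes (under-expressed in sensitive lines)
#' have expression correlated with sensitivity at `-r_planted`; planted OES
#' genes at `+r_planted`; all other genes are independent standard normals.
#'
#' @param n_lines number of cell lines.
#' @param n_genes number of human genes.
#' @param ues_genes,oes_genes character vectors of planted human gene names;
#'   they are added to the gene universe if not already among the
#'   `HUM...` background names.
#' @param r_planted magnitude of the planted expression-sensitivity
#'   correlation.
#' @param n_tissues number of tissue strata (labels `tissue_1`, ...).
#' @param seed integer seed.
#' @return list of class `"pharmaco_sim"`: `expression` (genes x lines
#'   matrix), `sensitivity` (named vector), `tissue` (named character),
#'   `truth` (list with `ues`, `oes`, `r`).
#' @export
simulate_pharmaco <- function(n_lines = 60, n_genes = 200,
                              ues_genes = character(0),
                              oes_genes = character(0),
                              r_planted = 0.6, n_tissues = 3, seed = 1) {
  set.seed(seed)
  lines <- sprintf("LINE%03d", seq_len(n_lines))
  genes <- unique(c(ues_genes, oes_genes, sprintf("HUM%04d", seq_len(n_genes))))
  sens <- stats::rnorm(n_lines)
  names(sens) <- lines
  s_std <- as.vector(scale(sens))
  expr <- matrix(stats::rnorm(length(genes) * n_lines), nrow = length(genes),
                 dimnames = list(genes, lines))
  mix <- function(sgn) sgn * r_planted * s_std +
    sqrt(1 - r_planted^2) * stats::rnorm(n_lines)
  for (g in ues_genes) expr[g, ] <- mix(-1)
  for (g in oes_genes) expr[g, ] <- mix(+1)
  tissue <- stats::setNames(
    sample(sprintf("tissue_%d", seq_len(n_tissues)), n_lines, replace = TRUE),
    lines)
  structure(list(expression = expr, sensitivity = sens, tissue = tissue,
                 truth = list(ues = ues_genes, oes = oes_genes,
                              r = r_planted)),
            class = "pharmaco_sim")
}

#' Simulate a yeast-human homology table
#'
#' Planted yeast genes each get a dedicated human partner (prefixed `"HS_"`)
#' with class `"one to one"`; a configurable fraction of additional edges of
#' classes `"one to many"` and `"many to many"` is drawn among the remaining
#' genes as background.
#'
#' @param yeast_genes yeast gene universe.
#' @param planted_yeast yeast genes that must have a human homolog.
#' @param n_background number of random background edges.
#' @param seed integer seed.
#' @return data.frame `yeast_gene`, `human_gene`, `homology_class`.
#' @export
simulate_homology <- function(yeast_genes, planted_yeast = character(0),
                              n_background = 50, seed = 1) {
  set.seed(seed)
  planted <- data.frame(yeast_gene = planted_yeast,
                        human_gene = paste0("HS_", planted_yeast),
                        homology_class = "one to one",
                        stringsAsFactors = FALSE)
  pool <- setdiff(yeast_genes, planted_yeast)
  n_background <- min(n_background, length(pool))
  yg <- sample(pool, n_background)
  bg <- data.frame(yeast_gene = yg,
                   human_gene = sprintf("HUM%04d", sample.int(200, n_background,
                                                              replace = TRUE)),
                   homology_class = sample(c("one to one", "one to many",
                                             "many to many"),
                                           n_background, replace = TRUE,
                                           prob = c(0.5, 0.3, 0.2)),
                   stringsAsFactors = FALSE)
  out <- rbind(planted, bg)
  out <- out[!duplicated(out[c("yeast_gene", "human_gene")]), ]
  rownames(out) <- NULL
  out
}

#' Generate the full synthetic input bundle
#'
#' Runs every generator with child seeds derived from the master seed:
#' phenomic time series with ground truth, GO annotations with planted
#' modules, a homology table linking planted yeast genes to human partners,
#' and two independent pharmacogenomic datasets (emulating two cell-line
#' panels) sharing the same planted UES/OES genes.
#'
#' Planted UES genes are the human partners of planted yeast enhancers with
#' effects in both media, and planted OES genes those of suppressors, so the
#' end-to-end prediction stage has known positives.
#'
#' @param config a [sim_config()] object.
#' @param n_lines cell lines per pharmacogenomic dataset.
#' @param n_human_genes background human genes per dataset.
#' @param r_planted planted expression-sensitivity correlation magnitude.
#' @param go_terms,go_planted,go_planted_size GO generator controls
#'   (see [simulate_go()]).
#' @param max_planted_predictions cap on planted UES (and OES) genes.
#' @return list of class `"synthetic_bundle"`.
#' @export
simulate_bundle <- function(config = sim_config(), n_lines = 60,
                            n_human_genes = 200, r_planted = 0.6,
                            go_terms = 40, go_planted = 3,
                            go_planted_size = 4,
                            max_planted_predictions = 5) {
  phen <- simulate_phenomics(config)
  truth <- phen$truth
  ann <- simulate_go(truth, n_terms = go_terms, n_planted = go_planted,
                     planted_size = go_planted_size,
                     seed = child_seed(config$seed, 2L))
  both <- function(cls) unique(truth$strain_id[truth$class == cls &
                                                 truth$scope == "both"])
  enh <- utils::head(both("enhancer"), max_planted_predictions)
  sup <- utils::head(both("suppressor"), max_planted_predictions)
  hom <- simulate_homology(unique(truth$strain_id), c(enh, sup),
                           seed = child_seed(config$seed, 3L))
  ues <- hom$human_gene[match(enh, hom$yeast_gene)]
  oes <- hom$human_gene[match(sup, hom$yeast_gene)]
  pharm <- list(
    panelA = simulate_pharmaco(n_lines, n_human_genes, ues, oes, r_planted,
                               seed = child_seed(config$seed, 4L)),
    panelB = simulate_pharmaco(n_lines, n_human_genes, ues, oes, r_planted,
                               seed = child_seed(config$seed, 5L)))
  structure(list(phenomic = phen, go = ann, homology = hom,
                 pharmaco = pharm,
                 truth = list(strains = truth, ues = ues, oes = oes,
                              planted_terms = attr(ann, "planted_terms")),
                 config = config),
            class = "synthetic_bundle")
}
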