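#' Define per-state expression programs
#'
#' Builds the mean-expression matrix for a set of discrete T cell states.
#' Every state receives a disjoint block of marker genes whose mean is
#' elevated `marker_fc`-fold over their baseline in all other states, so the
#' defining invariant (a marker's mean in its own state strictly exceeds its
#' mean in every other state) holds by construction.
#'
#' @param states character vector of state names. The default set mirrors the
#'   populations a splenic CD4 sort plus antigen-specific effectors contain:
#'   naive, ISG-high naive, TH1, TFH, pTCM and a CD8 contaminant.
#' @param n_genes total gene count, markers included.
#' @param n_markers markers per state.
#' @param marker_fc fold elevation of a marker in its own state.
#' @param base_meanlog,base_sdlog log-normal parameters of baseline per-gene
#'   means.
#' @param off_scale multiplier applied to a marker's baseline outside its own
#'   state (marker leak; 0 < off_scale < 1).
#' @param seed RNG seed for the baseline draw.
#'
#' @return list of class `state_programs`: `mu` (genes x states matrix),
#'   `markers` (named list of marker genes per state), `genes`, `states`.
#' @export
state_programs <- function(states = c("naive", "naive_ISG", "TH1", "TFH", "pTCM", "CD8"),
                           n_genes = 300, n_markers = 12, marker_fc = 6,
                           base_meanlog = 0, base_sdlog = 1,
                           off_scale = 0.25, seed = 1) {
  stopifnot(length(states) >= 1, n_markers * length(states) <= n_genes,
            marker_fc > 1, off_scale >= 0, off_scale < 1)
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  mu <- matrix(rep(base, length(states)), ncol = length(states),
               dimnames = list(genes, states))
  markers <- list()
  for (s in seq_along(states)) {
    idx <- ((s - 1) * n_markers + 1):(s * n_markers)
    mu[idx, ] <- mu[idx, ] * off_scale
    mu[idx, s] <- base[idx] * marker_fc
    markers[[states[s]]] <- genes[idx]
  }
  if (length(states) > 1) {
    stopifnot(all(vapply(seq_along(states), function(s) {
      all(mu[markers[[s]], s] >
            apply(mu[markers[[s]], -s, drop = FALSE], 1, max))
    }, logical(1))))
  }
  structure(list(mu = mu, markers = markers, genes = genes, states = states),
            class = "state_programs")
}

#' Simulation configuration for the expression generator
#'
#' @param n_cells named integer vector: cells per state (names must be states
#'   of the program set). For trajectory mode, a single unnamed total.
#' @param theta negative-binomial dispersion (size); `Inf` gives Poisson.
#' @param lib_sdlog log-normal sd of per-cell library-size factors
#'   (meanlog 0, so factors centre on 1).
#' @param dropout Bernoulli zeroing probability applied after sampling.
#' @param trajectory if TRUE, cells sit on a smooth 1-D path: a latent
#'   pseudotime tau ~ U(0,1) linearly interpolates the programs of
#'   `anchor_states`.
#' @param anchor_states two state names anchoring the trajectory.
#' @param mito_frac expected mitochondrial fraction injected via dedicated
#'   `mt-` genes (0 disables); `n_mito` such genes are appended.
#' @param n_mito number of mitochondrial genes when `mito_frac > 0`.
#' @param seed RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells, theta = 2, lib_sdlog = 0.3, dropout = 0.1,
                       trajectory = FALSE, anchor_states = NULL,
                       mito_frac = 0, n_mito = 5, seed = 1) {
  stopifnot(theta > 0, lib_sdlog >= 0, dropout >= 0, dropout < 1,
            mito_frac >= 0, mito_frac < 1, all(n_cells >= 0))
  structure(list(n_cells = n_cells, theta = theta, lib_sdlog = lib_sdlog,
                 dropout = dropout, trajectory = trajectory,
                 anchor_states = anchor_states, mito_frac = mito_frac,
                 n_mito = n_mito, seed = seed),
            class = "sim_config")
}

# NB draw that degrades gracefully to Poisson at theta = Inf.
.rnb <- function(n, mu, theta) {
  if (is.infinite(theta)) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = theta)
}

#' Simulate a UMI count matrix over discrete states or a smooth trajectory
#'
#' Counts are drawn as NB(l_i * mu_gs, theta) with per-cell library factor
#' l_i ~ logNormal(0, lib_sdlog), then thinned by Bernoulli dropout. True
#' state labels (and pseudotime, in trajectory mode) are recorded in
#' `cell_meta`.
#'
#' @param programs a [state_programs()] object.
#' @param config a [sim_config()].
#' @return a [cell_matrix()] with `cell_meta$state` (and `$tau` for
#'   trajectories).
#' @export
simulate_expression <- function(programs, config) {
  stopifnot(inherits(programs, "state_programs"), inherits(config, "sim_config"))
  set.seed(config$seed)
  mu <- programs$mu
  if (config$mito_frac > 0) {
    # mt- genes share the cell's expression scale so the injected fraction is
    # mito_frac of the expected total in every state
    tot <- colSums(mu)
    mt <- outer(rep(1 / config$n_mito, config$n_mito),
                tot * config$mito_frac / (1 - config$mito_frac))
    rownames(mt) <- sprintf("mt-gene%d", seq_len(config$n_mito))
    mu <- rbind(mu, mt)
  }
  if (isTRUE(config$trajectory)) {
    anchors <- config$anchor_states
    if (is.null(anchors)) anchors <- programs$states[1:2]
    if (!all(anchors %in% colnames(mu)) || length(anchors) != 2) {
      stop("trajectory mode needs two valid anchor states", call. = FALSE)
    }
    n <- sum(config$n_cells)
    tau <- stats::runif(n)
    cell_mu <- outer(1 - tau, mu[, anchors[1]]) + outer(tau, mu[, anchors[2]])
    state <- rep("trajectory", n)
  } else {
    nc <- config$n_cells
    if (is.null(names(nc))) stop("n_cells must be named by state", call. = FALSE)
    if (!all(names(nc) %in% colnames(mu))) {
      stop("unknown state(s) in n_cells: ",
           paste(setdiff(names(nc), colnames(mu)), collapse = ", "), call. = FALSE)
    }
    state <- rep(names(nc), nc)
    cell_mu <- t(mu[, state, drop = FALSE])
    tau <- NULL
    n <- length(state)
  }
  if (n == 0) stop("no cells requested", call. = FALSE)
  lib <- stats::rlnorm(n, 0, config$lib_sdlog)
  counts <- matrix(.rnb(n * nrow(mu), as.vector(lib * cell_mu), config$theta),
                   nrow = n)
  if (config$dropout > 0) {
    keep <- matrix(stats::rbinom(length(counts), 1, 1 - config$dropout),
                   nrow = n)
    counts <- counts * keep
  }
  ids <- sprintf("cell%05d", seq_len(n))
  meta <- data.frame(state = state, lib_factor = lib, row.names = ids)
  if (!is.null(tau)) meta$tau <- tau
  cell_matrix(counts, cell_ids = ids, gene_ids = rownames(mu), cell_meta = meta)
}

#' Simulate a smooth 1-D trajectory dataset
#'
#' The fixture for diffusion/imputation analyses: cells sit on a latent
#' pseudotime tau ~ U(0,1) and every gene's mean interpolates linearly
#' between two anchor programs drawn as independent log-normal per-gene
#' means, so the whole transcriptome varies smoothly along the manifold.
#' Counts are near-Poisson (theta = 10 by default): on a continuum the
#' biological variation is the trajectory itself and the residual count
#' noise is technical.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes.
#' @param theta NB dispersion of the count noise.
#' @param lib_sdlog,dropout library-size and dropout settings.
#' @param seed RNG seed (drives both the anchor programs and the counts).
#' @return a [cell_matrix()] with `cell_meta$tau` holding the latent
#'   pseudotime.
#' @export
simulate_trajectory <- function(n_cells = 1000, n_genes = 200, theta = 10,
                                lib_sdlog = 0.3, dropout = 0.1, seed = 1) {
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  mu <- cbind(start = stats::rlnorm(n_genes, 0, 1),
              end = stats::rlnorm(n_genes, 0, 1))
  rownames(mu) <- genes
  prog <- structure(list(mu = mu, markers = list(), genes = genes,
                         states = c("start", "end")),
                    class = "state_programs")
  cfg <- sim_config(n_cells = n_cells, theta = theta, lib_sdlog = lib_sdlog,
                    dropout = dropout, trajectory = TRUE,
                    anchor_states = c("start", "end"), seed = seed)
  simulate_expression(prog, cfg)
}

#' Archetype specification for clonotype simulation
#'
#' An archetype is a class of clonotypes sharing a phenotype probability
#' vector: members of each clone draw their fate i.i.d. from `p`. Defaults
#' follow the three fate-bias patterns seen in expanded antigen-specific
#' clones: TH1-biased, TFH-biased and mixed.
#'
#' @param name archetype label.
#' @param p named probability vector over phenotypes (sums to 1).
#' @param n_clones number of clones.
#' @param sizes explicit clone sizes (length `n_clones`), or NULL to draw
#'   zero-truncated geometric sizes.
#' @param rho success parameter of the zero-truncated geometric size draw.
#' @param min_size lower truncation applied to drawn sizes.
#' @return list of class `archetype_spec`.
#' @export
archetype_spec <- function(name, p, n_clones, sizes = NULL, rho = 0.15,
                           min_size = 1) {
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0), n_clones >= 1,
            rho > 0, rho < 1)
  if (!is.null(sizes)) stopifnot(length(sizes) == n_clones, all(sizes >= 1))
  structure(list(name = name, p = p, n_clones = n_clones, sizes = sizes,
                 rho = rho, min_size = min_size),
            class = "archetype_spec")
}

#' Default fate-bias archetypes
#'
#' @param n_clones clones per archetype.
#' @param sizes optional explicit sizes shared by all three archetypes.
#' @return list of three [archetype_spec()] objects (TH1_biased, TFH_biased,
#'   mixed) with phenotype probabilities (0.7, 0.1, 0.2), (0.1, 0.7, 0.2) and
#'   (0.4, 0.35, 0.25) over (TH1, TFH, pTCM).
#' @export
default_archetypes <- function(n_clones = 30, sizes = NULL) {
  list(
    archetype_spec("TH1_biased", c(TH1 = 0.7, TFH = 0.1, pTCM = 0.2),
                   n_clones, sizes = sizes),
    archetype_spec("TFH_biased", c(TH1 = 0.1, TFH = 0.7, pTCM = 0.2),
                   n_clones, sizes = sizes),
    archetype_spec("mixed", c(TH1 = 0.4, TFH = 0.35, pTCM = 0.25),
                   n_clones, sizes = sizes)
  )
}

# zero-truncated geometric on {1, 2, ...}
.rztgeom <- function(n, rho) 1L + stats::rgeom(n, rho)

#' Assign clonotypes over simulated cells
#'
#' For each clone, a size is drawn from its archetype's size distribution and
#' each member's phenotype is drawn i.i.d. from the archetype's probability
#' vector; members are then matched to distinct, previously unassigned cells
#' of that phenotype (phenotype-first assignment, so clones are dispersed
#' across the manifold within a phenotype rather than forming contiguous
#' blocks). Leftover cells stay unassigned.
#'
#' @param archetypes list of [archetype_spec()] objects.
#' @param state_labels named character vector: phenotype per cell (names are
#'   cell barcodes).
#' @param seed RNG seed.
#' @return a `clonotype_table` with columns barcode, clone_id, cdr3_nt, plus
#'   a `clone_info` attribute (clone_id, archetype, size).
#' @export
simulate_clonotypes <- function(archetypes, state_labels, seed = 1) {
  stopifnot(length(state_labels) > 0, !is.null(names(state_labels)))
  set.seed(seed)
  pool <- split(names(state_labels), state_labels)
  pool <- lapply(pool, sample)   # random draw order within each phenotype
  used <- lapply(pool, function(x) 0L)
  rows <- list(); info <- list(); clone_i <- 0L
  for (a in archetypes) {
    stopifnot(inherits(a, "archetype_spec"))
    sizes <- if (is.null(a$sizes)) {
      pmax(.rztgeom(a$n_clones, a$rho), a$min_size)
    } else a$sizes
    for (ci in seq_len(a$n_clones)) {
      clone_i <- clone_i + 1L
      id <- sprintf("clone%04d", clone_i)
      phen <- sample(names(a$p), sizes[ci], replace = TRUE, prob = a$p)
      tab <- table(phen)
      members <- character(0)
      for (ph in names(tab)) {
        need <- as.integer(tab[[ph]])
        have <- length(pool[[ph]]) - used[[ph]]
        if (is.null(pool[[ph]]) || have < need) {
          stop(sprintf(
            "clonotype demand exhausts '%s' cells (need %d more, %d available)",
            ph, need, max(have, 0)), call. = FALSE)
        }
        take <- pool[[ph]][(used[[ph]] + 1L):(used[[ph]] + need)]
        used[[ph]] <- used[[ph]] + need
        members <- c(members, take)
      }
      rows[[clone_i]] <- data.frame(barcode = members, clone_id = id,
                                    stringsAsFactors = FALSE)
      info[[clone_i]] <- data.frame(clone_id = id, archetype = a$name,
                                    size = sizes[ci], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  # opaque CDR3 nucleotide tag per clone, constant within a clone
  cdr3 <- vapply(unique(df$clone_id), function(id)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
    character(1))
  df$cdr3_nt <- cdr3[df$clone_id]
  out <- clonotype_table(df)
  attr(out, "clone_info") <- do.call(rbind, info)
  out
}

#' Simulate a CD4/CD8 T cell mixture over the nine-gene marker panel
#'
#' Generates the stand-in input for the CD8-purging classifier: a mixture in
#' which CD8-like cells express the Cd8a/Cd8b/Ccl5/Nkg7/Gzmm block and
#' CD4-like cells the Cd4/Cd40lg/Tnfrsf4/Itgb1 block, over a shared
#' background transcriptome. The true population is recorded in
#' `cell_meta$population`.
#'
#' @param n_cells total cells.
#' @param prop_cd4 CD4 mixture proportion.
#' @param marker_mean mean count of a marker in its own population.
#' @param leak mean count of a marker in the other population (0 = none).
#' @param n_background background genes with population-shared means.
#' @param theta NB dispersion; `Inf` for Poisson.
#' @param lib_sdlog library-size log-normal sd.
#' @param dropout Bernoulli zeroing probability.
#' @param sample_ids optional number of samples to spread cells over (adds a
#'   `sample` metadata column; the classifier fits per sample).
#' @param seed RNG seed.
#' @return a [cell_matrix()] containing the nine panel genes plus background.
#' @export
simulate_cd4cd8 <- function(n_cells = 1000, prop_cd4 = 0.5, marker_mean = 3,
                            leak = 0, n_background = 60, theta = 2,
                            lib_sdlog = 0.3, dropout = 0.2, sample_ids = 1,
                            seed = 1) {
  stopifnot(n_cells >= 2, prop_cd4 >= 0, prop_cd4 <= 1, marker_mean > 0,
            leak >= 0, dropout >= 0, dropout < 1)
  set.seed(seed)
  cd8_genes <- c("Cd8b", "Cd8a", "Ccl5", "Nkg7", "Gzmm")
  cd4_genes <- c("Cd4", "Cd40lg", "Tnfrsf4", "Itgb1")
  bg <- sprintf("bg%03d", seq_len(n_background))
  genes <- c(cd8_genes, cd4_genes, bg)
  n_cd4 <- round(n_cells * prop_cd4)
  pop <- c(rep("CD4", n_cd4), rep("CD8", n_cells - n_cd4))
  base_bg <- stats::rlnorm(n_background, 0, 1)
  mu <- matrix(0, nrow = length(genes), ncol = 2,
               dimnames = list(genes, c("CD4", "CD8")))
  mu[cd4_genes, "CD4"] <- marker_mean; mu[cd4_genes, "CD8"] <- leak
  mu[cd8_genes, "CD8"] <- marker_mean; mu[cd8_genes, "CD4"] <- leak
  mu[bg, ] <- base_bg
  lib <- stats::rlnorm(n_cells, 0, lib_sdlog)
  cell_mu <- t(mu[, pop, drop = FALSE]) * lib
  counts <- matrix(.rnb(length(cell_mu), as.vector(cell_mu), theta),
                   nrow = n_cells)
  if (dropout > 0) {
    counts <- counts * matrix(stats::rbinom(length(counts), 1, 1 - dropout),
                              nrow = n_cells)
  }
  ids <- sprintf("cell%05d", seq_len(n_cells))
  meta <- data.frame(population = pop,
                     sample = sprintf("s%d", rep_len(seq_len(sample_ids), n_cells)),
                     row.names = ids)
  cell_matrix(counts, cell_ids = ids, gene_ids = genes, cell_meta = meta)
}
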