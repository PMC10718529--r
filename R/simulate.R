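#' Simulate centered multi-view data with planted factors
#'
#' Generates scores Z ~ N(0,1) per group, weights W ~ N(0,1) per view
#' (zeroed where the activity pattern deactivates a (view, factor) pair)
#' and observations Y = Z W^T + noise. Optionally a fraction of samples
#' loses one randomly chosen view (NA rows). Each view is centered per
#' group before return so it satisfies the multiview_dataset contract;
#' the stored truth keeps the uncentered scores.
#'
#' @param n_samples named integer vector: samples per group (a single
#'   unnamed number makes one group `"g1"`).
#' @param views named integer vector: features per view.
#' @param K_true number of planted factors.
#' @param activity optional 0/1 matrix (views x factors). The default
#'   gives each factor a distinct active-view subset (factor 1 active
#'   everywhere, the next factors each silent in one view, then in pairs
#'   of views), mirroring how multicellular programs engage subsets of
#'   cell types; distinct patterns also make the planted factors
#'   identifiable beyond a rotation.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param missing_frac fraction of samples missing one random view.
#' @param seed RNG seed (bitwise reproducible).
#' @return list with `data` (a `multiview_dataset`) and `truth`
#'   (`Z` per group, `W` per view, `activity`).
#' @export
simulate_multiview <- function(n_samples = c(g1 = 50, g2 = 50),
                               views = c(v1 = 300, v2 = 300, v3 = 300),
                               K_true = 4, activity = NULL,
                               noise_sd = 0.3, missing_frac = 0, seed = 1) {
  stopifnot(K_true >= 1)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(names(n_samples)))
    names(n_samples) <- paste0("g", seq_along(n_samples))
  if (is.null(names(views))) names(views) <- paste0("v", seq_along(views))
  if (is.null(activity))
    activity <- default_activity(length(views), K_true,
                                 names(views))
  with_seed(seed, {
    gnames <- names(n_samples)
    Z <- lapply(gnames, function(g)
      matrix(rnorm(n_samples[g] * K_true), n_samples[g], K_true))
    names(Z) <- gnames
    for (g in gnames)
      rownames(Z[[g]]) <- sprintf("%s_s%02d", g, seq_len(n_samples[g]))
    W <- lapply(names(views), function(v) {
      w <- matrix(rnorm(views[v] * K_true), views[v], K_true)
      w <- sweep(w, 2, activity[v, ], "*")
      rownames(w) <- sprintf("%s_f%03d", v, seq_len(views[v]))
      w
    })
    names(W) <- names(views)
    samples <- unlist(lapply(Z, rownames), use.names = FALSE)
    groups <- setNames(rep(gnames, n_samples), samples)
    Ymats <- list()
    for (v in names(views)) {
      y <- do.call(rbind, lapply(gnames, function(g) Z[[g]] %*% t(W[[v]])))
      y <- y + matrix(rnorm(length(y), sd = noise_sd), nrow(y), ncol(y))
      rownames(y) <- samples
      colnames(y) <- rownames(W[[v]])
      Ymats[[v]] <- y
    }
    if (missing_frac > 0) {
      n_miss <- floor(missing_frac * length(samples))
      miss_samples <- sample(samples, n_miss)
      miss_view <- sample(names(views), n_miss, replace = TRUE)
      for (i in seq_len(n_miss))
        Ymats[[miss_view[i]]][miss_samples[i], ] <- NA_real_
    }
    transform <- list()
    for (v in names(views)) {
      transform[[v]] <- list()
      for (g in gnames) {
        rows <- samples[groups == g]
        obs <- rows[!is.na(Ymats[[v]][rows, 1])]
        mu <- colMeans(Ymats[[v]][obs, , drop = FALSE])
        Ymats[[v]][obs, ] <- sweep(Ymats[[v]][obs, , drop = FALSE], 2, mu, "-")
        transform[[v]][[g]] <- list(center = mu, scale = NULL)
      }
    }
    data <- structure(list(views = Ymats, sample_ids = samples,
                           groups = groups,
                           view_kind = setNames(rep("expression",
                                                    length(views)),
                                                names(views)),
                           transform = transform,
                           dropped_features = list(), scaled = FALSE),
                      class = "multiview_dataset")
    list(data = data, truth = list(Z = Z, W = W, activity = activity))
  })
}

## Distinct active-view subsets per factor: all views, then each
## single view left out, then each pair left out; cycles if exhausted.
default_activity <- function(M, K, vnames) {
  pats <- list(rep(1, M))
  if (M >= 2) {
    for (i in seq_len(M)) { p <- rep(1, M); p[i] <- 0; pats <- c(pats, list(p)) }
    if (M >= 3)
      for (i in seq_len(M - 1)) for (j in seq(i + 1, M)) {
        p <- rep(1, M); p[c(i, j)] <- 0; pats <- c(pats, list(p))
      }
  }
  act <- matrix(unlist(lapply(seq_len(K), function(k)
    pats[[(k - 1L) %% length(pats) + 1L]])), nrow = M,
    dimnames = list(vnames, NULL))
  act
}

#' Simulate an annotated single-cell atlas with planted structure
#'
#' Emulates the structure of cross-condition single-cell atlases: several
#' samples per condition, a handful of cell types each with functional
#' cell states, planted cell-type and cell-state marker genes, planted
#' condition-driven multicellular program genes (up- and down-regulated
#' per cell type, shifting all states alike), and ambient contamination:
#' every cell's sampling probabilities are a (1-lambda)/lambda mixture of
#' its own profile and the cell-weighted mean profile of the whole pool,
#' so markers of one cell type leak into the pseudobulks of the others.
#'
#' Counts per cell are Multinomial(depth, probabilities) with log-normal
#' depth. With `lambda = 0` cell-type markers are structural zeros outside
#' their own type.
#'
#' @param types cell-type names.
#' @param states_per_type number of states within each type.
#' @param n_genes size of the gene universe.
#' @param conditions condition labels (first = reference).
#' @param n_samples_per_condition samples per condition.
#' @param n_cells cells per (sample, cell type).
#' @param lambda ambient contamination rate in [0, 0.5].
#' @param effect_fold multiplicative condition effect on program genes.
#' @param markers_per_type,markers_per_state,program_up,program_down
#'   planted gene counts.
#' @param depth_meanlog,depth_sdlog log-normal depth distribution.
#' @param seed RNG seed.
#' @return list with `cells` (a [cell_profiles]) and `truth` (planted
#'   marker/state/program gene lists, lambda, effect sizes).
#' @export
simulate_single_cell <- function(types = c("CT1", "CT2", "CT3"),
                                 states_per_type = 2, n_genes = 300,
                                 conditions = c("healthy", "disease"),
                                 n_samples_per_condition = 10,
                                 n_cells = 60, lambda = 0.1,
                                 effect_fold = 3,
                                 markers_per_type = 10,
                                 markers_per_state = 8,
                                 program_up = 12, program_down = 8,
                                 depth_meanlog = log(2500),
                                 depth_sdlog = 0.3, seed = 1) {
  stopifnot(lambda >= 0, lambda <= 0.5, effect_fold > 0)
  nt <- length(types)
  need <- nt * (markers_per_type + states_per_type * markers_per_state +
                program_up + program_down)
  assert_that(need < n_genes, "gene universe too small for planted structure")
  genes <- sprintf("gene%03d", seq_len(n_genes))
  with_seed(seed, {
    ## carve up the universe
    pool <- seq_len(n_genes)
    take <- function(n) { idx <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; idx }
    type_markers <- state_markers <- prog_up <- prog_dn <- list()
    for (t in types) {
      type_markers[[t]] <- genes[take(markers_per_type)]
      state_markers[[t]] <- list()
      for (s in seq_len(states_per_type))
        state_markers[[t]][[paste0(t, "_state", s)]] <- genes[take(markers_per_state)]
      prog_up[[t]] <- genes[take(program_up)]
      prog_dn[[t]] <- genes[take(program_down)]
    }
    base <- rlnorm(n_genes, meanlog = 0, sdlog = 0.4)
    names(base) <- genes
    base[unlist(type_markers)] <- base[unlist(type_markers)] * 5
    base[c(unlist(prog_up), unlist(prog_dn))] <-
      base[c(unlist(prog_up), unlist(prog_dn))] * 2

    ## profile per (type, state, condition)
    profile <- function(t, s, cond) {
      r <- base
      for (t2 in setdiff(types, t)) r[type_markers[[t2]]] <- 0
      r[type_markers[[t]]] <- r[type_markers[[t]]] * 2
      st_name <- paste0(t, "_state", s)
      for (s2 in names(state_markers[[t]]))
        if (s2 == st_name) r[state_markers[[t]][[s2]]] <-
            r[state_markers[[t]][[s2]]] * 5
      if (cond != conditions[1]) {
        r[prog_up[[t]]] <- r[prog_up[[t]]] * effect_fold
        r[prog_dn[[t]]] <- r[prog_dn[[t]]] / effect_fold
      }
      r / sum(r)
    }
    profs <- list()
    for (t in types) for (s in seq_len(states_per_type))
      for (cond in conditions)
        profs[[paste(t, s, cond, sep = ".")]] <- profile(t, s, cond)

    ## cell table
    meta <- list()
    for (cond in conditions) for (i in seq_len(n_samples_per_condition)) {
      sid <- sprintf("%s_s%02d", cond, i)
      for (t in types) {
        st <- sample(rep_len(seq_len(states_per_type), n_cells))
        meta[[paste(sid, t)]] <- data.frame(
          sample_id = sid, cell_type = t,
          cell_state = paste0(t, "_state", st),
          condition = cond, stringsAsFactors = FALSE)
      }
    }
    meta <- do.call(rbind, meta)
    rownames(meta) <- sprintf("cell%05d", seq_len(nrow(meta)))
    key <- paste(meta$cell_type,
                 sub("^.*_state", "", meta$cell_state),
                 meta$condition, sep = ".")
    pmat <- do.call(rbind, profs[key])          # cells x genes
    ambient <- colMeans(pmat)
    pmix <- (1 - lambda) * pmat + lambda *
      matrix(ambient, nrow(pmat), n_genes, byrow = TRUE)
    if (max(abs(rowSums(pmix) - 1)) > 1e-8)
      stop("cell probabilities failed to normalize")
    depth <- pmax(1, round(rlnorm(nrow(meta), depth_meanlog, depth_sdlog)))
    counts <- t(vapply(seq_len(nrow(meta)), function(i)
      as.vector(rmultinom(1, depth[i], pmix[i, ])), numeric(n_genes)))
    dimnames(counts) <- list(rownames(meta), genes)
    cells <- cell_profiles(counts, meta)
    list(cells = cells,
         truth = list(type_markers = type_markers,
                      state_markers = state_markers,
                      program_up = prog_up, program_down = prog_dn,
                      lambda = lambda, effect_fold = effect_fold,
                      conditions = conditions))
  })
}

#' Simulate spatial slides with planted program activation regions
#'
#' Each slide is a rectangular spot grid. Spot cell-type proportions are
#' drawn from niche-specific Dirichlet distributions (the grid is split
#' into vertical niche bands, each favoring one cell type). On case
#' slides, a contiguous fraction of the spots where the target cell type
#' is present (proportion >= `prop_threshold`) is activated: program
#' genes are shifted there (+`effect` for up genes, -`effect` for down
#' genes, on the log-normalized scale).
#'
#' @param n_per_condition named vector, slides per condition; names are
#'   the condition labels and activation is planted in all but the first.
#' @param grid c(rows, cols) of the spot lattice (>= 4x4).
#' @param types cell-type names.
#' @param n_genes gene universe size.
#' @param target_type cell type carrying the planted program.
#' @param program_up,program_down planted program gene counts.
#' @param activation_frac fraction of effective spots activated on case
#'   slides.
#' @param effect additive shift on activated spots.
#' @param prop_threshold presence threshold used to define effective spots
#'   in the stored truth (default 0.1).
#' @param seed RNG seed.
#' @return list with `slides` (list of `spatial_slide`) and `truth`
#'   (signature weights, per-spot activation masks, per-slide true
#'   relative areas).
#' @export
simulate_slides <- function(n_per_condition = c(control = 3, case = 3),
                            grid = c(12, 12),
                            types = c("CT1", "CT2", "CT3"),
                            n_genes = 300, target_type = "CT1",
                            program_up = 12, program_down = 8,
                            activation_frac = 0.4, effect = 2.5,
                            prop_threshold = 0.1, seed = 1) {
  stopifnot(all(grid >= 4), activation_frac >= 0, activation_frac <= 1)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  up <- genes[seq_len(program_up)]
  dn <- genes[program_up + seq_len(program_down)]
  sig_w <- c(setNames(rep(1, program_up), up),
             setNames(rep(-1, program_down), dn))
  with_seed(seed, {
    mu_g <- rnorm(n_genes, 3, 1)
    n_spots <- prod(grid)
    coords <- expand.grid(x = seq_len(grid[2]), y = seq_len(grid[1]))
    niche <- cut(coords$x, breaks = length(types), labels = FALSE)
    slides <- list()
    masks <- list()
    true_area <- c()
    for (cond in names(n_per_condition)) {
      for (i in seq_len(n_per_condition[cond])) {
        id <- sprintf("%s_slide%d", cond, i)
        alpha <- matrix(1, n_spots, length(types))
        alpha[cbind(seq_len(n_spots), niche)] <- 6
        props <- t(apply(alpha, 1, function(a) {
          g <- rgamma(length(a), a); g / sum(g)
        }))
        colnames(props) <- types
        expr <- matrix(rep(mu_g, each = n_spots), n_spots, n_genes) +
                matrix(rnorm(n_spots * n_genes, 0, 0.8), n_spots, n_genes)
        ## expression is reported per-gene centered within the slide, so a
        ## signature's score reflects planted activation rather than the
        ## baseline offset of whichever genes it happens to contain
        expr <- sweep(expr, 2, colMeans(expr))
        colnames(expr) <- genes
        rownames(expr) <- rownames(props) <-
          sprintf("%s_spot%03d", id, seq_len(n_spots))
        active <- rep(FALSE, n_spots)
        if (cond != names(n_per_condition)[1]) {
          eff_spots <- which(props[, target_type] >= prop_threshold)
          n_act <- round(activation_frac * length(eff_spots))
          if (n_act > length(eff_spots))
            stop("activation region exceeds grid")
          ## contiguous region: lowest x-coordinates first
          act <- eff_spots[order(coords$x[eff_spots],
                                 coords$y[eff_spots])][seq_len(n_act)]
          expr[act, up] <- expr[act, up] + effect
          expr[act, dn] <- expr[act, dn] - effect
          active[act] <- TRUE
        }
        eff <- sum(props[, target_type] >= prop_threshold)
        slides[[id]] <- structure(list(slide_id = id, expr = expr,
                                       props = props,
                                       coords = as.matrix(coords),
                                       condition = cond),
                                  class = "spatial_slide")
        masks[[id]] <- active
        true_area[id] <- if (eff > 0) sum(active) / eff else NA_real_
      }
    }
    list(slides = slides,
         truth = list(signature_weights = sig_w, target_type = target_type,
                      activation_mask = masks, relative_area = true_area,
                      program_up = up, program_down = dn))
  })
}

#' Simulate a bulk transcriptomics cohort convolving composition and program
#'
#' Bulk profiles are mixtures of cell-type reference profiles weighted by
#' per-sample Dirichlet compositions; planted program genes are
#' multiplicatively shifted in case samples (coordinated multicellular
#' response); multiplicative log-normal noise is applied.
#'
#' @param n_per_condition named vector of samples per condition (first
#'   level is the reference; the effect is planted in the others).
#' @param types cell-type names.
#' @param n_genes gene universe size.
#' @param composition_alpha Dirichlet parameters per condition (named list
#'   of numeric vectors, or a single vector reused for all conditions).
#' @param program_up,program_down planted program gene counts.
#' @param effect_fold multiplicative shift of program genes in case samples.
#' @param noise_sdlog log-normal noise sd.
#' @param seed RNG seed.
#' @return list with `study` (a `bulk_study`: gene x sample `expr`,
#'   `condition`, `study_id`) and `truth` (compositions, program genes,
#'   signature weights).
#' @export
simulate_bulk_cohort <- function(n_per_condition = c(nf = 15, hf = 15),
                                 types = c("CT1", "CT2", "CT3"),
                                 n_genes = 300,
                                 composition_alpha = c(8, 6, 4),
                                 program_up = 12, program_down = 8,
                                 effect_fold = 3, noise_sdlog = 0.2,
                                 seed = 1) {
  genes <- sprintf("gene%03d", seq_len(n_genes))
  up <- genes[seq_len(program_up)]
  dn <- genes[program_up + seq_len(program_down)]
  if (!is.list(composition_alpha))
    composition_alpha <- setNames(rep(list(composition_alpha),
                                      length(n_per_condition)),
                                  names(n_per_condition))
  with_seed(seed, {
    profiles <- matrix(rlnorm(n_genes * length(types), 2, 0.6),
                       n_genes, length(types),
                       dimnames = list(genes, types))
    samples <- character(0); cond <- character(0)
    comp <- NULL; expr <- NULL
    for (cd in names(n_per_condition)) {
      a <- composition_alpha[[cd]]
      for (i in seq_len(n_per_condition[cd])) {
        sid <- sprintf("%s_s%02d", cd, i)
        g <- rgamma(length(types), a)
        fr <- g / sum(g)
        if (abs(sum(fr) - 1) > 1e-8) stop("fractions do not sum to 1")
        x <- as.vector(profiles %*% fr)
        if (cd != names(n_per_condition)[1]) {
          x[match(up, genes)] <- x[match(up, genes)] * effect_fold
          x[match(dn, genes)] <- x[match(dn, genes)] / effect_fold
        }
        x <- x * rlnorm(n_genes, 0, noise_sdlog)
        samples <- c(samples, sid); cond <- c(cond, cd)
        comp <- rbind(comp, fr); expr <- cbind(expr, x)
      }
    }
    dimnames(expr) <- list(genes, samples)
    rownames(comp) <- samples; colnames(comp) <- types
    sig_w <- c(setNames(rep(1, length(up)), up),
               setNames(rep(-1, length(dn)), dn))
    study <- structure(list(study_id = "synthetic_cohort", expr = expr,
                            condition = setNames(cond, samples),
                            platform = "synthetic"),
                       class = "bulk_study")
    list(study = study,
         truth = list(compositions = comp, program_up = up,
                      program_down = dn, signature_weights = sig_w))
  })
}
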