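# Synthetic embryo generator: icosphere blastomeres placed in canonical
# 4-cell arrangements, or packed by relaxation for 8-cell embryos. Real
# blastomeres are not spheres; this is a declared simplification that gives
# every downstream stage a known ground-truth contact graph.

canonical_centers <- function(name, r) {
  switch(name,
    tetrahedral = rbind( # regular tetrahedron, edge 2r: all six pairs touch
      c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * (r / sqrt(2)),
    planar = rbind( # square of side 2r: diagonals 2*sqrt(2)*r stay apart
      c(-r, -r, 0), c(r, -r, 0), c(r, r, 0), c(-r, r, 0)),
    linear = rbind(
      c(0, 0, 0), c(2 * r, 0, 0), c(4 * r, 0, 0), c(6 * r, 0, 0)),
    closed_y = rbind( # equilateral triangle edge 2r + pendant on the apex
      c(0, 0, 0), c(2 * r, 0, 0), c(r, r * sqrt(3), 0),
      c(r, r * sqrt(3) + 2 * r, 0)),
    pseudotetrahedral = rbind( # tetrahedron with one edge stretched to 2.2r,
      c(-1.1 * r, 0, 0),       # breaking exactly that contact at factor 1.05
      c(1.1 * r, 0, 0),
      c(0, r * sqrt(4 - 1.21 - 1), r),
      c(0, r * sqrt(4 - 1.21 - 1), -r)),
    abort(sprintf("unknown arrangement '%s'", name), "invalid_parameter")
  )
}

#' Specification for a synthetic embryo
#'
#' @param name One of `"tetrahedral"`, `"pseudotetrahedral"`, `"planar"`,
#'   `"closed_y"`, `"linear"`, `"packed_n8"`, `"custom"`.
#' @param n_cells Number of blastomeres (4 for the named arrangements,
#'   8 default for `packed_n8`).
#' @param radius_mean Mean blastomere radius (nominally micrometres; default
#'   1, i.e. radii are expressed in units of the mean radius).
#' @param radius_cv Coefficient of variation of radii (default 0: equal
#'   cells, mirroring the even-blastomere morphology of gradable embryos).
#' @param jitter_sd SD of isotropic Gaussian positional noise added to each
#'   center, same units as the radius (default 0).
#' @param mesh_subdivisions Icosphere refinement level (default 2).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @param centers For `name = "custom"`: explicit matrix of sphere centers.
#' @return An object of class `arrangement_spec`.
#' @export
arrangement_spec <- function(name, n_cells = if (name == "packed_n8") 8L else 4L,
                             radius_mean = 1, radius_cv = 0, jitter_sd = 0,
                             mesh_subdivisions = 2, seed = 1, centers = NULL) {
  known <- c("tetrahedral", "pseudotetrahedral", "planar", "closed_y",
             "linear", "packed_n8", "custom")
  if (!is.character(name) || length(name) != 1L || !(name %in% known)) {
    abort(sprintf("unknown arrangement name '%s'", paste(name, collapse = ",")),
          "invalid_parameter")
  }
  check_positive_scalar(radius_mean, "radius_mean")
  if (!is_scalar_num(radius_cv) || radius_cv < 0) {
    abort("`radius_cv` must be >= 0", "invalid_parameter")
  }
  if (!is_scalar_num(jitter_sd) || jitter_sd < 0) {
    abort("`jitter_sd` must be >= 0", "invalid_parameter")
  }
  if (name %in% c("tetrahedral", "pseudotetrahedral", "planar", "closed_y",
                  "linear") && n_cells != 4L) {
    abort("named four-cell arrangements require n_cells = 4", "invalid_parameter")
  }
  if (name == "custom" && is.null(centers)) {
    abort("custom arrangements need explicit `centers`", "invalid_parameter")
  }
  structure(list(name = name, n_cells = as.integer(n_cells),
                 radius_mean = radius_mean, radius_cv = radius_cv,
                 jitter_sd = jitter_sd,
                 mesh_subdivisions = as.integer(mesh_subdivisions),
                 seed = as.integer(seed), centers = centers),
            class = "arrangement_spec")
}

#' Generate a synthetic embryo
#'
#' Builds one icosphere mesh per blastomere at the canonical centers of the
#' requested arrangement (or a relaxed sphere packing for `packed_n8`), with
#' optional radius variability and positional jitter. With `jitter_sd = 0`
#' and `radius_cv = 0` the mesh-pipeline contact network at scale factor 1.05
#' reproduces the arrangement's Hickman vector exactly; the canonical
#' geometries keep every pair at least 0.1 radius away from the tangency
#' band, so small jitter cannot flip contacts.
#'
#' @param spec An [arrangement_spec()].
#' @param embryo_id Optional identifier (defaults to name + seed).
#' @return An `embryo` whose ground-truth sphere centers and radii are
#'   attached as attributes `centers` and `radii`.
#' @export
generate_arrangement <- function(spec, embryo_id = NULL) {
  if (!inherits(spec, "arrangement_spec")) {
    abort("`spec` must be an arrangement_spec", "invalid_parameter")
  }
  r <- spec$radius_mean
  with_seed(spec$seed, {
    radii <- rep(r, spec$n_cells)
    if (spec$radius_cv > 0) {
      repeat {
        radii <- stats::rnorm(spec$n_cells, r, spec$radius_cv * r)
        if (all(radii > 0.2 * r)) break
      }
    }
    centers <- switch(spec$name,
      packed_n8 = pack_spheres(spec$n_cells, radii, seed = NULL),
      custom = as.matrix(spec$centers),
      canonical_centers(spec$name, r)
    )
    if (nrow(centers) != spec$n_cells) {
      abort("`centers` must have one row per cell", "invalid_parameter")
    }
    if (spec$jitter_sd > 0) {
      centers <- centers +
        matrix(stats::rnorm(3 * spec$n_cells, 0, spec$jitter_sd), ncol = 3)
    }
    meshes <- lapply(seq_len(spec$n_cells), function(i) {
      icosphere(radii[i], centers[i, ], spec$mesh_subdivisions,
                cell_id = sprintf("c%d", i))
    })
    if (is.null(embryo_id)) {
      embryo_id <- sprintf("%s_s%d", spec$name, spec$seed)
    }
    emb <- embryo(meshes, embryo_id = embryo_id)
    attr(emb, "centers") <- centers
    attr(emb, "radii") <- radii
    emb
  })
}

#' Pack n spheres into a connected, non-overlapping cluster
#'
#' Stochastic relaxation emulating a compacted cell aggregate. Each round the
#' cluster is contracted toward its centroid (a weak central attraction
#' standing in for the zona pellucida that confines real blastomeres),
#' perturbed by Gaussian jitter whose amplitude decays to zero (so the
#' cluster can escape chain- and ring-shaped local minima early on), and
#' pairwise overlaps are resolved by pushing offending pairs apart to
#' tangency. A final noise-free polish phase contracts until the scale-1.05
#' contact graph is stable for 10 rounds. The result has no pair overlapping
#' at scale 1.0 beyond `1e-6 * mean(radii)` and a connected contact graph at
#' scale 1.05; for four equal spheres it lands on (pseudo)tetrahedral
#' packings in almost every seed.
#'
#' @param n Number of spheres (>= 2).
#' @param radii Positive radii, length `n` (or scalar, recycled).
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @param n_anneal Annealing rounds (default 150).
#' @param max_iter Polish-phase iteration cap (default 200).
#' @return `n x 3` matrix of centers.
#' @export
pack_spheres <- function(n, radii, seed = 1, n_anneal = 150, max_iter = 200) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) abort("`n` must be >= 2", "invalid_parameter")
  radii <- rep_len(as.numeric(radii), n)
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    abort("`radii` must be positive", "invalid_parameter")
  }
  rm_ <- mean(radii)
  tol <- 1e-6 * rm_
  with_seed(seed, {
    centers <- matrix(stats::rnorm(3 * n, 0, 0.6 * rm_), ncol = 3)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    rsum <- radii[pairs[, 1]] + radii[pairs[, 2]]

    pair_dist <- function(ctr) {
      d <- ctr[pairs[, 1], , drop = FALSE] - ctr[pairs[, 2], , drop = FALSE]
      sqrt(rowSums(d^2))
    }
    resolve <- function(ctr) {
      for (sweep_i in 1:200) {
        moved <- FALSE
        for (k in seq_len(nrow(pairs))) {
          i <- pairs[k, 1]; j <- pairs[k, 2]
          dv <- ctr[i, ] - ctr[j, ]
          d <- sqrt(sum(dv^2))
          target <- rsum[k] + tol / 2
          if (d < rsum[k] - tol) {
            u <- if (d < 1e-12) stats::rnorm(3) else dv / d
            u <- u / sqrt(sum(u^2))
            push <- (target - d) / 2
            ctr[i, ] <- ctr[i, ] + u * push
            ctr[j, ] <- ctr[j, ] - u * push
            moved <- TRUE
          }
        }
        if (!moved) break
      }
      ctr
    }
    contract <- function(ctr, f) {
      ctr0 <- colMeans(ctr)
      sweep(sweep(ctr, 2, ctr0) * f, 2, ctr0, "+")
    }
    connected <- function(adj) {
      g <- igraph::make_empty_graph(n, directed = FALSE)
      if (any(adj)) {
        g <- igraph::add_edges(g, t(matrix(c(pairs[adj, 1], pairs[adj, 2]),
                                           ncol = 2)))
      }
      igraph::count_components(g) == 1L
    }

    for (it in seq_len(n_anneal)) {
      sig <- 0.25 * rm_ * exp(-4 * it / n_anneal)
      centers <- contract(centers, 0.93)
      centers <- centers + matrix(stats::rnorm(3 * n, 0, sig), ncol = 3)
      centers <- resolve(centers)
    }

    prev <- NULL
    stable <- 0L
    for (it in seq_len(max_iter)) {
      centers <- resolve(contract(centers, 0.95))
      adj <- pair_dist(centers) < 1.05 * rsum
      stable <- if (!is.null(prev) && identical(adj, prev)) stable + 1L else 0L
      prev <- adj
      if (stable >= 10L && connected(adj) &&
          max(rsum - pair_dist(centers)) < tol) {
        return(centers)
      }
    }
    if (connected(prev) && max(rsum - pair_dist(centers)) < tol) {
      return(centers)
    }
    abort(sprintf(
      "sphere packing did not converge (residual overlap %.3g)",
      max(0, max(rsum - pair_dist(centers)))), "convergence_error")
  })
}

# outcome simulation -------------------------------------------------------

#' Outcome simulation models
#'
#' Two forms. The two-group form draws biomarker values for a positive and a
#' negative outcome group from Gaussians with the given means/SDs (the shape
#' in which clinical cohorts report the contact biomarker), truncating to
#' `range` by resampling so values respect the [0, N-1] bound of mean
#' contacts. The logistic form labels supplied biomarker values x positive
#' with probability `plogis(intercept + slope * x)`, encoding the premise
#' that more intercellular contact means greater developmental potential.
#'
#' @param mean_pos,sd_pos,n_pos Mean, SD and size of the positive-outcome group.
#' @param mean_neg,sd_neg,n_neg Same for the negative-outcome group.
#' @param range Truncation interval for biomarker values (default `c(0, 7)`,
#'   the attainable range at the eight-cell stage).
#' @param intercept,slope Logistic model coefficients on the biomarker.
#' @return An object of class `outcome_model`.
#' @export
outcome_model_two_group <- function(mean_pos, sd_pos, n_pos,
                                    mean_neg, sd_neg, n_neg,
                                    range = c(0, 7)) {
  if (sd_pos <= 0 || sd_neg <= 0) abort("SDs must be > 0", "invalid_parameter")
  if (n_pos < 2 || n_neg < 2) abort("group sizes must be >= 2", "invalid_parameter")
  structure(list(type = "two_group", mean_pos = mean_pos, sd_pos = sd_pos,
                 n_pos = as.integer(n_pos), mean_neg = mean_neg,
                 sd_neg = sd_neg, n_neg = as.integer(n_neg), range = range),
            class = "outcome_model")
}

#' @rdname outcome_model_two_group
#' @export
outcome_model_logistic <- function(intercept, slope) {
  if (!is_scalar_num(intercept) || !is.numeric(slope) || length(slope) != 1L ||
      is.na(slope)) {
    abort("`intercept` and `slope` must be single numbers", "invalid_parameter")
  }
  structure(list(type = "logistic", intercept = intercept, slope = slope),
            class = "outcome_model")
}

rnorm_trunc <- function(n, mean, sd, range) {
  out <- stats::rnorm(n, mean, sd)
  for (rep_i in 1:100) {
    bad <- out < range[1] | out > range[2]
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Simulate binary clinical outcomes
#'
#' @param model An [outcome_model_two_group()] or [outcome_model_logistic()].
#' @param biomarker Biomarker values (required for the logistic form; ignored
#'   by the two-group form, which generates value/label pairs directly).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `value` (biomarker) and `label`
#'   (integer 0/1).
#' @export
simulate_outcomes <- function(model, biomarker = NULL, seed = NULL) {
  if (!inherits(model, "outcome_model")) {
    abort("`model` must be an outcome_model", "invalid_parameter")
  }
  with_seed(seed, {
    if (model$type == "two_group") {
      pos <- rnorm_trunc(model$n_pos, model$mean_pos, model$sd_pos, model$range)
      neg <- rnorm_trunc(model$n_neg, model$mean_neg, model$sd_neg, model$range)
      df <- data.frame(value = c(pos, neg),
                       label = rep(c(1L, 0L), c(model$n_pos, model$n_neg)))
      # shuffle so group membership is not encoded in row order
      df[sample.int(nrow(df)), , drop = FALSE]
    } else {
      if (is.null(biomarker)) {
        abort("the logistic form requires `biomarker` values", "invalid_parameter")
      }
      # a step classifier at threshold theta is the slope -> Inf limit with
      # intercept = -slope * theta; use a large finite slope to realize it
      eta <- model$intercept + model$slope * biomarker
      p <- stats::plogis(eta)
      if (any(is.na(p) | p < 0 | p > 1)) {
        abort("invalid outcome probabilities", "invalid_parameter")
      }
      data.frame(value = biomarker,
                 label = as.integer(stats::runif(length(p)) < p))
    }
  })
}

#' Sample synthetic Gardner grades
#'
#' Draws grade strings from a small categorical distribution spanning the
#' good/poor dichotomy (good: expansion >= 3 with ICM and TE in A-B).
#'
#' @param n Number of grades.
#' @param p_good Probability of a good-quality grade (default 0.55, the
#'   good/poor balance seen in graded clinical cohorts).
#' @param seed Optional seed.
#' @return Character vector of Gardner grade strings.
#' @export
sample_gardner <- function(n, p_good = 0.55, seed = NULL) {
  good <- c("3AB", "4AA", "4AB", "4BB", "5AB")
  poor <- c("1", "2AA", "2BC", "3BC", "3CB")
  with_seed(seed, {
    ifelse(stats::runif(n) < p_good,
           sample(good, n, replace = TRUE),
           sample(poor, n, replace = TRUE))
  })
}
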