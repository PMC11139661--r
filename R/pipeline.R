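# End-to-end orchestration: meshes -> contact networks -> descriptors ->
# group statistics -> cross-validated prediction, with a reproducible
# manifest. Timestamps are deliberately never written, so reruns under the
# same config are byte-identical.

#' Pipeline run configuration
#'
#' @param input_dir Directory of embryo subdirectories (one per embryo), or
#'   `NULL` to generate a synthetic cohort.
#' @param synthetic List of arguments for [synthetic_cohort()] when
#'   `input_dir` is `NULL`.
#' @param scale_factor Mesh scale factor for contact detection (default
#'   1.05). Values outside (1, 1.5] trigger a warning: below 1 detects
#'   nothing but pre-existing overlap, far above 1.5 links everything.
#' @param stage_filter `"t4"`, `"t8"` or `"both"`.
#' @param comparisons Outcome columns for the group-statistics stage.
#' @param cv_outcomes Outcome columns for the cross-validation stage.
#' @param cv_folds,cv_seed Cross-validation settings.
#' @param output_dir Where run artifacts are written.
#' @param seed Master seed for synthetic generation.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir = NULL, synthetic = list(),
                       scale_factor = 1.05, stage_filter = "both",
                       comparisons = c("quality"), cv_outcomes = character(),
                       cv_folds = 5, cv_seed = 1, output_dir = tempfile("run"),
                       seed = 1) {
  check_positive_scalar(scale_factor, "scale_factor")
  if (scale_factor <= 1 || scale_factor > 1.5) {
    warning(sprintf("scale_factor %.3g outside the recommended (1, 1.5] range",
                    scale_factor))
  }
  if (!stage_filter %in% c("t4", "t8", "both")) {
    abort("`stage_filter` must be 't4', 't8' or 'both'", "invalid_parameter")
  }
  structure(list(input_dir = input_dir, synthetic = synthetic,
                 scale_factor = scale_factor, stage_filter = stage_filter,
                 comparisons = comparisons, cv_outcomes = cv_outcomes,
                 cv_folds = as.integer(cv_folds), cv_seed = as.integer(cv_seed),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Generate a synthetic cohort of embryos with outcomes
#'
#' Four-cell embryos are drawn across the five canonical arrangements;
#' eight-cell embryos come from the sphere packer. Outcome labels are
#' simulated from a logistic model on the (ground-truth) mean-contacts
#' biomarker, so the cohort carries the association the pipeline is meant to
#' detect; Gardner grades are sampled to match the induced quality label.
#'
#' @param n Number of embryos.
#' @param stage 4 or 8.
#' @param arrangements For stage 4: probability weights over the five named
#'   arrangements (default: frequencies echoing observed four-cell cohorts,
#'   pseudotetrahedral and tetrahedral dominant).
#' @param jitter_sd Positional jitter SD in mean-radius units (default 0.02:
#'   visible noise, well inside the 0.1-radius contact margin).
#' @param logistic_intercept,logistic_slope Outcome model on mean contacts.
#' @param seed Master seed.
#' @return List with `embryos` (list of `embryo`) and `outcomes` (data.frame
#'   of simulated labels).
#' @export
synthetic_cohort <- function(n, stage = 4,
                             arrangements = c(pseudotetrahedral = 0.38,
                                              tetrahedral = 0.32,
                                              planar = 0.11,
                                              closed_y = 0.07,
                                              linear = 0.05,
                                              custom_other = 0.07),
                             jitter_sd = 0.02,
                             logistic_intercept = -4, logistic_slope = 1.8,
                             seed = 1) {
  stage <- as.integer(stage)
  if (!stage %in% c(4L, 8L)) abort("`stage` must be 4 or 8", "invalid_parameter")
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, n)
    if (stage == 4L) {
      names_pool <- sample(names(arrangements), n, replace = TRUE,
                           prob = arrangements)
    } else {
      names_pool <- rep("packed_n8", n)
    }
    embryos <- lapply(seq_len(n), function(i) {
      nm <- names_pool[i]
      if (nm == "custom_other") {
        # triangle + isolated cell: a graphical vector outside the named five
        r <- 1
        ctr <- rbind(c(0, 0, 0), c(2 * r, 0, 0), c(r, r * sqrt(3), 0),
                     c(5 * r, 5 * r, 0))
        spec <- arrangement_spec("custom", 4L, jitter_sd = jitter_sd,
                                 seed = seeds[i], centers = ctr)
      } else {
        spec <- arrangement_spec(nm, if (stage == 4L) 4L else 8L,
                                 jitter_sd = jitter_sd, seed = seeds[i])
      }
      generate_arrangement(spec, embryo_id = sprintf("emb%04d", i))
    })
    # ground-truth biomarker from analytic sphere contacts
    mc <- vapply(embryos, function(e) {
      mean_contacts(analytic_contact_network(attr(e, "centers"),
                                             attr(e, "radii")))
    }, numeric(1))
    model <- outcome_model_logistic(logistic_intercept, logistic_slope)
    blast <- simulate_outcomes(model, mc)$label
    preg <- simulate_outcomes(model, mc)$label
    lb <- ifelse(preg == 1L, simulate_outcomes(model, mc)$label, 0L)
    gardner <- sample_gardner(n)
    outcomes <- data.frame(
      embryo_id = vapply(embryos, `[[`, character(1), "embryo_id"),
      blastulated = as.logical(blast),
      gardner = gardner,
      quality = gardner_quality(gardner),
      transferred = TRUE,
      biochemical_pregnancy = as.logical(preg),
      live_birth = as.logical(lb),
      miscarriage = as.logical(preg == 1L & lb == 0L &
                                 stats::runif(n) < 0.15),
      euploid = stats::runif(n) < 0.75,
      stringsAsFactors = FALSE
    )
    list(embryos = embryos, outcomes = outcomes)
  })
}

#' Analytic contact network of a sphere configuration
#'
#' The ground-truth oracle for generated embryos: spheres i and j are in
#' contact iff the center distance is strictly below
#' `scale_factor * (r_i + r_j)`.
#'
#' @param centers `n x 3` matrix of sphere centers.
#' @param radii Radii, length n.
#' @param scale_factor Contact scale factor (default 1.05).
#' @return A `contact_network`.
#' @export
analytic_contact_network <- function(centers, radii, scale_factor = 1.05) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  radii <- rep_len(as.numeric(radii), n)
  edges <- matrix(integer(), 0, 2)
  if (n >= 2L) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d <- sqrt(rowSums((centers[pairs[, 1], , drop = FALSE] -
                         centers[pairs[, 2], , drop = FALSE])^2))
    hit <- d < scale_factor * (radii[pairs[, 1]] + radii[pairs[, 2]])
    edges <- cbind(pairs[hit, 1], pairs[hit, 2])
  }
  contact_network_obj(max(n, 1L), edges)
}

#' Per-embryo descriptor table
#'
#' Builds contact networks for a list of embryos and tabulates the package's
#' descriptors: Hickman vector, mean contacts per blastomere and (for 4-cell
#' embryos) the arrangement nickname.
#'
#' @param embryos List of `embryo` objects.
#' @param scale_factor Contact scale factor (default 1.05).
#' @return List with `descriptors` (data.frame), `networks` (list of
#'   `contact_network`), and `exclusions` (data.frame of embryo_id + reason
#'   code for embryos whose meshes failed validation).
#' @export
describe_embryos <- function(embryos, scale_factor = 1.05) {
  rows <- list()
  nets <- list()
  excl <- list()
  for (e in embryos) {
    net <- tryCatch(contact_network(e, scale_factor), blastonet_error = function(err) err)
    if (inherits(net, "condition")) {
      reason <- if (inherits(net, "blastonet_invalid_mesh")) "degenerate_mesh"
                else "invalid_embryo"
      excl[[length(excl) + 1]] <- data.frame(embryo_id = e$embryo_id,
                                             reason = reason,
                                             detail = conditionMessage(net),
                                             stringsAsFactors = FALSE)
      next
    }
    hv <- hickman_vector(net)
    rows[[length(rows) + 1]] <- data.frame(
      embryo_id = e$embryo_id,
      stage = e$stage,
      hickman_vector = format_hickman(hv),
      mean_contacts = mean_contacts(net),
      arrangement = if (e$stage == 4L) classify_arrangement_4cell(hv)
                    else NA_character_,
      stringsAsFactors = FALSE
    )
    nets[[e$embryo_id]] <- net
  }
  list(
    descriptors = if (length(rows)) do.call(rbind, rows) else
      data.frame(embryo_id = character(), stage = integer(),
                 hickman_vector = character(), mean_contacts = numeric(),
                 arrangement = character(), stringsAsFactors = FALSE),
    networks = nets,
    exclusions = if (length(excl)) do.call(rbind, excl) else
      data.frame(embryo_id = character(), reason = character(),
                 detail = character(), stringsAsFactors = FALSE)
  )
}

#' Run the full analysis pipeline
#'
#' Executes mesh -> network -> descriptor -> statistics -> cross-validation
#' on either a directory of embryos or a generated synthetic cohort, writing
#' all artifacts (descriptor CSV, arrangement frequency tables, group-test
#' CSV, CV CSV/JSON, GraphML networks, and a JSON manifest echoing the
#' config) under `config$output_dir`. Embryos failing mesh validation are
#' excluded with a reason code and listed in `exclusions.csv`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the in-memory artifacts.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    abort("`config` must be a run_config", "invalid_parameter")
  }
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage_tag <- function(s) paste0("t", s)

  # --- input stage ---------------------------------------------------------
  if (!is.null(config$input_dir)) {
    dirs <- list.dirs(config$input_dir, recursive = FALSE)
    if (!length(dirs)) {
      abort(sprintf("input stage: no embryo directories in %s",
                    config$input_dir), "invalid_input")
    }
    embryos <- list()
    read_excl <- list()
    for (d in dirs) {
      e <- tryCatch(read_embryo_dir(d), blastonet_error = function(err) err)
      if (inherits(e, "condition")) {
        read_excl[[length(read_excl) + 1]] <-
          data.frame(embryo_id = basename(d), reason = "unreadable_mesh",
                     detail = conditionMessage(e), stringsAsFactors = FALSE)
      } else {
        embryos[[length(embryos) + 1]] <- e
      }
    }
    outcomes <- do.call(rbind, Filter(Negate(is.null), lapply(embryos, function(e) {
      if (is.null(e$metadata)) return(NULL)
      as.data.frame(lapply(unclass(e$metadata), function(v) v),
                    stringsAsFactors = FALSE)
    })))
  } else {
    syn_args <- config$synthetic
    syn_args$seed <- config$seed
    cohort <- do.call(synthetic_cohort, syn_args)
    embryos <- cohort$embryos
    outcomes <- cohort$outcomes
    read_excl <- list()
  }

  if (config$stage_filter != "both") {
    want <- if (config$stage_filter == "t4") 4L else 8L
    embryos <- Filter(function(e) e$stage == want, embryos)
  }
  if (!length(embryos)) {
    abort("input stage: no embryos to analyse", "invalid_input")
  }

  # --- descriptor stage ----------------------------------------------------
  desc <- describe_embryos(embryos, config$scale_factor)
  exclusions <- rbind(do.call(rbind, c(read_excl, list(NULL))), desc$exclusions)
  descriptors <- desc$descriptors
  if (!is.null(outcomes)) {
    descriptors <- merge(descriptors, outcomes, by = "embryo_id", all.x = TRUE,
                         sort = TRUE)
  }
  descriptors <- descriptors[order(descriptors$embryo_id), , drop = FALSE]
  utils::write.csv(descriptors, file.path(out, "descriptors.csv"),
                   row.names = FALSE)
  if (!is.null(exclusions) && nrow(exclusions)) {
    utils::write.csv(exclusions, file.path(out, "exclusions.csv"),
                     row.names = FALSE)
  }

  net_dir <- file.path(out, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (id in names(desc$networks)) {
    write_graphml(desc$networks[[id]], file.path(net_dir, paste0(id, ".graphml")))
  }

  # --- arrangement frequencies ---------------------------------------------
  freq <- list()
  for (s in sort(unique(descriptors$stage))) {
    ids <- descriptors$embryo_id[descriptors$stage == s]
    tab <- arrangement_frequencies(desc$networks[ids])
    freq[[stage_tag(s)]] <- tab
    utils::write.csv(tab, file.path(out, sprintf("frequencies_%s.csv",
                                                 stage_tag(s))),
                     row.names = FALSE)
  }

  # --- group statistics -----------------------------------------------------
  stats_tab <- NULL
  comps <- intersect(config$comparisons, names(descriptors))
  if (length(comps)) {
    stats_tab <- do.call(rbind, lapply(comps, function(cmp) {
      tryCatch(compare_outcome(descriptors, cmp),
               blastonet_error = function(e) NULL)
    }))
    if (!is.null(stats_tab)) {
      utils::write.csv(stats_tab, file.path(out, "group_tests.csv"),
                       row.names = FALSE)
    }
  }

  # --- cross-validation -----------------------------------------------------
  cv_reports <- list()
  for (oc in intersect(config$cv_outcomes, names(descriptors))) {
    dat <- descriptors[!is.na(descriptors[[oc]]), , drop = FALSE]
    rep_ <- tryCatch(
      cross_validate(dat$mean_contacts, dat[[oc]], k = config$cv_folds,
                     seed = config$cv_seed, outcome_name = oc,
                     feature_name = "mean_contacts"),
      blastonet_error = function(e) NULL)
    if (!is.null(rep_)) cv_reports[[oc]] <- rep_
  }
  if (length(cv_reports)) {
    cv_tab <- do.call(rbind, lapply(cv_reports, function(r) {
      data.frame(outcome = r$outcome_name, metric = r$summary$metric,
                 mean = r$summary$mean, sd = r$summary$sd,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(cv_tab, file.path(out, "cv_summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(cv_reports, function(r) {
        list(outcome = r$outcome_name, k = r$k, seed = r$seed,
             folds = r$folds, summary = r$summary)
      }),
      file.path(out, "cv_report.json"), dataframe = "rows", auto_unbox = TRUE,
      digits = NA)
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    package = "blastonet",
    version = as.character(utils::packageVersion("blastonet")),
    config = unclass(config),
    n_embryos = length(embryos),
    n_analysed = nrow(desc$descriptors),
    n_excluded = if (is.null(exclusions)) 0L else nrow(exclusions)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  invisible(list(descriptors = descriptors, networks = desc$networks,
                 frequencies = freq, group_tests = stats_tab,
                 cv_reports = cv_reports, exclusions = exclusions,
                 output_dir = out))
}
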