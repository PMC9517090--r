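#' Configuration of a single accuracy case
#'
#' Bundles everything needed to evaluate one plan/postop pair: the two
#' meshes (as file paths or in-memory [triangle_mesh()] objects), the two
#' ROI definitions (resolved on the planned model; the resulting vertex
#' indices are applied to both meshes, which therefore must share vertex
#' ordering — true for phantom pairs and for STL pairs exported from a
#' common template; supply `roi1_t1` to override), ICP settings, and the
#' acceptability threshold.
#'
#' @param t0,t1 STL paths or [triangle_mesh()] objects (plan, postop).
#' @param roi1,roi2 ROI inputs: an `roi_selection`, a definition list (see
#'   [read_roi_definition()]) or a JSON path.
#' @param icp an [icp_params()] set.
#' @param signed_deviation measure signed deviations (requires consistent
#'   reference winding).
#' @param acceptability_threshold clinical band half-width in mm.
#' @param operator_id label recorded in outputs.
#' @param roi1_t1 optional override ROI input for the postop mesh.
#' @param case_id label.
#' @param seed integer seed (ICP subsampling, ROI jitter).
#' @return A `case_config` list.
#' @export
case_config <- function(t0, t1, roi1, roi2, icp = icp_params(),
                        signed_deviation = FALSE,
                        acceptability_threshold = 2,
                        operator_id = "op1", roi1_t1 = NULL,
                        case_id = "case", seed = 1L) {
  if (acceptability_threshold <= 0) {
    stop("acceptability_threshold must be > 0", call. = FALSE)
  }
  structure(list(t0 = t0, t1 = t1, roi1 = roi1, roi2 = roi2, icp = icp,
                 signed_deviation = signed_deviation,
                 acceptability_threshold = acceptability_threshold,
                 operator_id = operator_id, roi1_t1 = roi1_t1,
                 case_id = case_id, seed = as.integer(seed)),
            class = "case_config")
}

load_mesh_input <- function(x, stage) {
  m <- if (inherits(x, "triangle_mesh")) x
       else if (is.character(x)) read_stl(x)
       else stop(stage, ": expected a triangle_mesh or an STL path",
                 call. = FALSE)
  validate_mesh(m)
}

load_roi_input <- function(x, mesh, stage) {
  if (inherits(x, "roi_selection")) x
  else if (is.character(x)) resolve_roi(read_roi_definition(x), mesh)
  else if (is.list(x)) resolve_roi(x, mesh)
  else stop(stage, ": expected an roi_selection, definition list or path",
            call. = FALSE)
}

#' Run the full accuracy analysis for one case
#'
#' The per-case procedure: read and validate both meshes, resolve ROI1 and
#' ROI2 on the plan, coarsely align the postop reference region onto the
#' plan's ([initial_alignment()]), refine with trimmed point-to-mesh ICP
#' ([icp_refine()]), apply the resulting transform to the whole postop mesh,
#' measure the maxillary deviation field against the planned maxillary
#' sub-mesh ([surface_deviation()]), summarise it and classify the RMS 3D
#' error against the clinical band. The measurement direction is
#' achieved-vs-planned (postop points against the plan surface); pass the
#' meshes swapped for the reverse reading.
#'
#' @param config a [case_config()].
#' @param output_dir if given, writes `<case>_points.csv` (per-point table),
#'   `<case>_summary.csv`, `<case>_colormap.ply` and `<case>_log.txt` there.
#' @return A list: `case` (one-row tibble: `case_id`, `operator_id`,
#'   `rms_3d_error`, `max_dev`, `min_dev`, `mean_dev`, `n_points`,
#'   `acceptable`, `converged`), `deviation` (`deviation_result`),
#'   `registration` (`registration_report`), `transform` (the T1-to-T0
#'   [rigid_transform()]), `log` (character).
#' @export
run_case <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "case_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed for case '", config$case_id, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  t0 <- stage("read-t0", load_mesh_input(config$t0, "t0"))
  t1 <- stage("read-t1", load_mesh_input(config$t1, "t1"))
  note("case=", config$case_id, " operator=", config$operator_id)
  note("t0 vertices=", n_vertices(t0), " faces=", n_faces(t0))
  note("t1 vertices=", n_vertices(t1), " faces=", n_faces(t1))
  t0 <- compute_normals(t0)
  roi1 <- stage("roi1", load_roi_input(config$roi1, t0, "roi1"))
  roi2 <- stage("roi2", load_roi_input(config$roi2, t0, "roi2"))
  roi1_t1 <- if (is.null(config$roi1_t1)) {
    if (n_vertices(t1) != n_vertices(t0)) {
      stop("t0 and t1 vertex counts differ (", n_vertices(t0), " vs ",
           n_vertices(t1), "); supply `roi1_t1` to define the postop ",
           "reference region explicitly", call. = FALSE)
    }
    roi_from_indices(t1, roi1$vertex_indices, roi1$name)
  } else {
    stage("roi1-t1", load_roi_input(config$roi1_t1, t1, "roi1_t1"))
  }
  note("roi1 vertices=", length(roi1$vertex_indices),
       " roi2 vertices=", length(roi2$vertex_indices))

  src <- extract_points(t1, roi1_t1)$points
  tgt <- extract_points(t0, roi1)$points
  init <- stage("initial-alignment", initial_alignment(src, tgt))
  note("initial_alignment rotation_deg=",
       sprintf("%.4f", rotation_angle(init)))
  ref1 <- stage("roi1-submesh", extract_submesh(t0, roi1))
  reg <- stage("icp", icp_refine(src, ref1, init = init,
                                 params = config$icp))
  if (!reg$converged) {
    warning("ICP did not converge for case '", config$case_id, "' within ",
            config$icp$max_iterations, " iterations", call. = FALSE)
  }
  note("icp iterations=", reg$iterations_run, " converged=", reg$converged,
       " final_rms=", sprintf("%.6g", utils::tail(reg$rms_per_iteration, 1)),
       " pairs=", reg$correspondences_used)

  t1_aligned <- transform_mesh(t1, reg$final_transform)
  ref2 <- stage("roi2-submesh", {
    sm <- extract_submesh(t0, roi2)
    compute_normals(sm)
  })
  samples <- t1_aligned$vertices[roi2$vertex_indices, , drop = FALSE]
  dev <- stage("deviation",
               surface_deviation(samples, ref2,
                                 signed = config$signed_deviation,
                                 reference_region = roi2$name))
  rms <- dev$summary$rms
  acceptable <- classify_acceptability(rms, config$acceptability_threshold)
  note("rms_3d_error=", sprintf("%.6g", rms), " threshold=",
       config$acceptability_threshold, " acceptable=", acceptable)

  case_row <- tibble::tibble(
    case_id = config$case_id, operator_id = config$operator_id,
    rms_3d_error = rms, max_dev = dev$summary$max_dev,
    min_dev = dev$summary$min_dev, mean_dev = dev$summary$mean_dev,
    n_points = dev$summary$n_points, acceptable = acceptable,
    converged = reg$converged)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(output_dir, config$case_id)
    readr::write_csv(tidy(dev), paste0(base, "_points.csv"))
    readr::write_csv(case_row, paste0(base, "_summary.csv"))
    region <- extract_submesh(t1_aligned, roi2)
    dev_region <- surface_deviation(region$vertices, ref2,
                                    signed = config$signed_deviation,
                                    reference_region = roi2$name)
    deviation_colormap(region, dev_region, paste0(base, "_colormap.ply"),
                       palette_range = config$acceptability_threshold)
    writeLines(log, paste0(base, "_log.txt"))
  }
  list(case = case_row, deviation = dev, registration = reg,
       transform = reg$final_transform, log = log)
}

#' Run replicate measurements and average them
#'
#' Runs each replicate configuration (same case measured by different
#' operators, e.g. with jittered ROI boundaries) and averages the RMS 3D
#' errors ([average_operators()]) into a single case-level result.
#'
#' @param configs non-empty list of [case_config()]s for the same case.
#' @param output_dir forwarded to [run_case()].
#' @return A list: `case` (one-row tibble with `rms_3d_error` the operator
#'   average and `operator_values` a list-column of per-operator RMS),
#'   `replicates` (list of full [run_case()] results).
#' @export
run_operator_replicates <- function(configs, output_dir = NULL) {
  if (length(configs) == 0L) stop("no replicate configurations",
                                  call. = FALSE)
  runs <- vector("list", length(configs))
  failures <- character(0)
  for (i in seq_along(configs)) {
    runs[[i]] <- tryCatch(run_case(configs[[i]], output_dir = output_dir),
                          error = function(e) conditionMessage(e))
    if (is.character(runs[[i]])) {
      failures <- c(failures,
                    paste0(configs[[i]]$operator_id, ": ", runs[[i]]))
    }
  }
  if (length(failures)) {
    stop("replicate failures:\n  ", paste(failures, collapse = "\n  "),
         call. = FALSE)
  }
  per_op <- vapply(runs, function(r) r$case$rms_3d_error, 0)
  avg <- if (length(per_op) == 1L) per_op else average_operators(per_op)
  first <- runs[[1]]$case
  case_row <- tibble::tibble(
    case_id = first$case_id,
    rms_3d_error = avg,
    operator_values = list(per_op),
    n_operators = length(per_op),
    acceptable = classify_acceptability(
      avg, configs[[1]]$acceptability_threshold))
  list(case = case_row, replicates = runs)
}

#' Jitter a predicate ROI definition
#'
#' Perturbs the boundary parameters of a predicate ROI definition (box
#' corners, sphere radius/centre, halfspace offset) by Gaussian noise of
#' `sd` mm — the reproducible analogue of different operators hand-painting
#' slightly different region boundaries.
#'
#' @param definition a predicate ROI definition list.
#' @param sd boundary jitter (mm).
#' @param seed integer seed.
#' @return The jittered definition list.
#' @export
jitter_roi_definition <- function(definition, sd = 1, seed = 1L) {
  if (identical(definition$type, "indices")) {
    stop("only predicate ROI definitions can be jittered", call. = FALSE)
  }
  withr::with_seed(seed, {
    j <- function(x) x + stats::rnorm(length(x), 0, sd)
    d <- definition
    if (d$type == "box") { d$lo <- j(d$lo); d$hi <- j(d$hi) }
    if (d$type == "sphere") { d$center <- j(d$center)
                              d$radius <- max(1e-6, j(d$radius)) }
    if (d$type == "halfspace") d$offset <- j(d$offset)
    d
  })
}

#' Run a cohort and its group contrasts
#'
#' Applies [run_case()] to every row of a cohort manifest and computes, for
#' each requested contrast (`"all"`, `"monobloc"`, `"segmental"`), the
#' per-group summary and the two-group comparison of the 3D errors. The
#' comparison defaults to the independent pooled t-test: the protocol this
#' mirrors names a paired ("coupled samples") test, but the two technique
#' arms contain different patients, so an independent test is the defensible
#' default (a warning notes the substitution).
#'
#' @param manifest a tibble/data.frame with columns `case_id`, `group`,
#'   `subgroup` and either a `pair` list-column (from
#'   [generate_cohort()]) or path columns `t0_path`, `t1_path`,
#'   `roi1_path`, `roi2_path`. A path to a TSV manifest is also accepted.
#' @param contrasts subset of `c("all", "monobloc", "segmental")`.
#' @param icp an [icp_params()] set used for every case.
#' @param alpha significance level for the contrasts.
#' @param output_dir forwarded to [run_case()].
#' @return A list: `cases` (tibble of per-case results joined with group
#'   labels), `contrasts` (named list of `group_comparison` objects; a
#'   contrast with fewer than 2 cases per group is skipped with a warning),
#'   `summaries` (tibble: contrast x group means/SDs/n).
#' @export
run_cohort <- function(manifest,
                       contrasts = c("all", "monobloc", "segmental"),
                       icp = icp_params(), alpha = 0.05,
                       output_dir = NULL) {
  if (is.character(manifest)) {
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE)
  }
  manifest <- tibble::as_tibble(manifest)
  need <- c("case_id", "group", "subgroup")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$case_id)) {
    stop("duplicate case_id in manifest", call. = FALSE)
  }
  groups <- unique(manifest$group)
  if (length(groups) != 2L) {
    stop("manifest must contain exactly 2 groups, found ",
         length(groups), call. = FALSE)
  }
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  warning("group comparison uses the independent pooled t-test; the ",
          "clinical protocol names a paired test, undefined across ",
          "independent patient groups", call. = FALSE)
  results <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    cfg <- if ("pair" %in% names(manifest)) {
      pair <- row$pair[[1]]
      case_config(pair$t0, pair$t1, pair$truth$roi1, pair$truth$roi2,
                  icp = icp, case_id = row$case_id)
    } else {
      case_config(row$t0_path, row$t1_path, row$roi1_path, row$roi2_path,
                  icp = icp, case_id = row$case_id)
    }
    run_case(cfg, output_dir = output_dir)
  })
  cases <- dplyr::bind_cols(
    manifest[, c("case_id", "group", "subgroup")],
    dplyr::bind_rows(lapply(results, function(r) r$case[, -1]))
  )
  comp <- list()
  summ <- list()
  for (ct in contrasts) {
    sel <- if (ct == "all") cases else cases[cases$subgroup == ct, ]
    a <- sel$rms_3d_error[sel$group == groups[1]]
    b <- sel$rms_3d_error[sel$group == groups[2]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("contrast '", ct, "' skipped: fewer than 2 cases per group",
              call. = FALSE)
      next
    }
    gc <- t_test(a, b, mode = "independent-pooled", alpha = alpha,
                 group_labels = groups)
    comp[[ct]] <- gc
    summ[[ct]] <- dplyr::mutate(tidy(gc), contrast = ct, .before = 1)
  }
  list(cases = cases, contrasts = comp,
       summaries = dplyr::bind_rows(summ), results = results)
}
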