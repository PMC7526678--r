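# Orchestration: per-specimen pipeline (registration or injected ground-truth
# fields -> mesh -> frame/regions -> strain -> regional medians) and the
# study-level driver assembling a cohort table and running the statistics
# battery.  Configurations are plain lists, loadable from YAML/JSON.

#' Read a study configuration from YAML or JSON
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return the configuration list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)  # YAML is a superset of JSON
}

#' Run the image-to-strain pipeline for one specimen
#'
#' Stages: (optional) rigid alignment to the unloaded reference, ROI crop,
#' non-rigid registration (skipped when a ground-truth displacement field is
#' injected: phantom mode), hexahedral meshing of the mask, cylindrical frame
#' from a circle fit (supplied rim points or auto-extracted), regional
#' division, strain computation, and regional median extraction per load
#' level. Deterministic given its inputs.
#'
#' @param mask a [label_mask()] of the meniscus on the unloaded grid.
#' @param unloaded the unloaded [image_volume()] (may be `NULL` in phantom
#'   mode).
#' @param loads named list, one entry per load level, each either
#'   `list(field = <displacement_field>)` (phantom mode) or
#'   `list(image = <image_volume>)` to be registered.
#' @param circle_points optional n x 2 matrix of outer-rim points (mm) for
#'   the circle fit; when `NULL` they are auto-extracted from the body
#'   elements.
#' @param line_a,line_p [separation_line()]s dividing off the attachments;
#'   when `NULL` and the mask carries ARA/PRA labels, lines are placed at the
#'   label boundaries.
#' @param roi optional [roi_box()] applied to all volumes before
#'   registration.
#' @param registration a [registration_config()].
#' @param rigid run the rigid pre-alignment stage (needs `unloaded`).
#' @param measure strain measure, see [strain_tensor()].
#' @param inner_fraction,angular_bin zone-splitting parameters, see
#'   [split_zones()].
#' @param verbose log stage progress.
#' @return list with `summaries` (named per load: [regional_medians()]
#'   tables), `fields` (displacement fields used), `mesh`, `frame`,
#'   `labeling`.
#' @export
run_specimen <- function(mask, unloaded = NULL, loads,
                         circle_points = NULL, line_a = NULL, line_p = NULL,
                         roi = NULL,
                         registration = registration_config(),
                         rigid = FALSE,
                         measure = "infinitesimal",
                         inner_fraction = 2 / 3, angular_bin = 5,
                         verbose = FALSE) {
  stopifnot(inherits(mask, "label_mask"), is.list(loads), length(loads) > 0)
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(roi)) {
    mask <- crop_to_roi(mask, roi)
    if (!is.null(unloaded)) unloaded <- crop_to_roi(unloaded, roi)
  }
  mesh <- mask_to_hexmesh(mask)
  say("meshed %d elements", nrow(mesh$elements))
  if (is.null(circle_points))
    circle_points <- outer_rim_points(mesh,
                                      body_labels = meniscus_labels()[["BODY"]])
  cf <- fit_circle(circle_points)
  frame <- build_frame(cf$center, radius_fit = cf$radius)
  if (is.null(line_a) || is.null(line_p)) {
    ll <- .lines_from_labels(mesh, frame)
    if (is.null(line_a)) line_a <- ll$line_a
    if (is.null(line_p)) line_p <- ll$line_p
  }
  labeling <- label_regions(mesh, frame, line_a, line_p,
                            inner_fraction = inner_fraction,
                            angular_bin = angular_bin)
  fields <- list()
  summaries <- list()
  for (nm in names(loads)) {
    entry <- loads[[nm]]
    if (!is.null(entry$field)) {
      fld <- entry$field
      if (!is.null(roi)) fld <- crop_to_roi(fld, roi)
      say("load %s: ground-truth field injected, registration skipped", nm)
    } else {
      if (is.null(unloaded))
        stop("registration mode needs the unloaded image", call. = FALSE)
      mov <- entry$image
      if (rigid) {
        rr <- rigid_register(mask, mov, fixed_image = unloaded)
        mov <- rr$resampled
        say("load %s: rigid alignment done", nm)
      } else if (!is.null(roi)) {
        mov <- crop_to_roi(mov, roi)
      }
      fld <- nonrigid_register(unloaded, mov, registration,
                               verbose = verbose)
      say("load %s: non-rigid registration done", nm)
    }
    nodal <- sample_nodal_displacements(fld, mesh)
    sf <- compute_strain_field(mesh, nodal, frame, measure)
    summaries[[nm]] <- regional_medians(sf, labeling)
    fields[[nm]] <- fld
  }
  list(summaries = summaries, fields = fields, mesh = mesh, frame = frame,
       labeling = labeling)
}

# Separation lines at the angular boundaries between BODY and the labeled
# attachments, from the mask labels carried on the mesh elements.
.lines_from_labels <- function(mesh, frame) {
  lab <- meniscus_labels()
  if (!all(c(lab[["ARA"]], lab[["PRA"]]) %in% mesh$labels))
    stop("mask has no ARA/PRA labels: supply separation lines explicitly",
         call. = FALSE)
  cyl <- to_cylindrical(frame, element_centroids(mesh))
  th_body <- cyl$theta[mesh$labels == lab[["BODY"]]]
  pick <- function(att_label) {
    th_att <- cyl$theta[mesh$labels == att_label]
    # work relative to the attachment's circular mean: the separation line
    # sits halfway between the attachment's body-facing end and the nearest
    # body element
    ref <- atan2(mean(sin(th_att)), mean(cos(th_att)))
    a_rel <- (th_att - ref + pi) %% (2 * pi) - pi
    b_rel <- (th_body - ref + pi) %% (2 * pi) - pi
    b_near <- b_rel[which.min(abs(b_rel))]
    a_end <- if (b_near >= 0) max(a_rel) else min(a_rel)
    ref + (a_end + b_near) / 2
  }
  list(line_a = separation_line(pick(lab[["ARA"]]), "anterior"),
       line_p = separation_line(pick(lab[["PRA"]]), "posterior"))
}

#' Run a whole (synthetic or real) study
#'
#' Executes [run_specimen()] per specimen entry, concatenates the regional
#' summaries into a cohort table of characteristic strains and runs the
#' statistics battery. Specimen failures are reported and the statistics run
#' on the surviving set.
#'
#' @param specimens named list; each entry is a list with the arguments of
#'   [run_specimen()] plus metadata `group` (`"mild"`/`"severe"`),
#'   `side` (`"medial"`/`"lateral"`), `kl_grade`, and `load_levels` (named
#'   numeric vector mapping the load names of `loads` to body-weight
#'   fractions).
#' @param stats a [stats_config()], or `NULL` to skip the statistics.
#' @param verbose log progress.
#' @return list with `cohort` (cohort table data.frame), `report`
#'   (stats report or `NULL`), `failures` (named list of error messages) and
#'   `results` (per-specimen pipeline outputs).
#' @export
run_study <- function(specimens, stats = stats_config(), verbose = FALSE) {
  stopifnot(is.list(specimens), length(specimens) > 0)
  rows <- list()
  results <- list()
  failures <- list()
  for (id in names(specimens)) {
    sp <- specimens[[id]]
    res <- tryCatch(
      run_specimen(mask = sp$mask, unloaded = sp$unloaded, loads = sp$loads,
                   circle_points = sp$circle_points, line_a = sp$line_a,
                   line_p = sp$line_p, roi = sp$roi,
                   registration = if (is.null(sp$registration))
                     registration_config() else sp$registration,
                   rigid = isTRUE(sp$rigid),
                   measure = if (is.null(sp$measure)) "infinitesimal"
                   else sp$measure,
                   verbose = verbose),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      warning("specimen ", id, " failed: ", failures[[id]], call. = FALSE)
      next
    }
    results[[id]] <- res
    for (nm in names(res$summaries)) {
      s <- res$summaries[[nm]]
      load <- if (!is.null(sp$load_levels)) sp$load_levels[[nm]] else NA_real_
      s_zone <- s[s$zone != "all" | s$region %in% c("ARA", "PRA"), ]
      zone <- ifelse(s_zone$region %in% c("ARA", "PRA"), "attachment",
                     s_zone$zone)
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = id, group = sp$group,
        kl_grade = if (is.null(sp$kl_grade)) NA_integer_ else sp$kl_grade,
        side = sp$side, load = load, region = s_zone$region, zone = zone,
        direction = s_zone$direction, strain_pct = s_zone$median,
        stringsAsFactors = FALSE)
    }
  }
  cohort <- if (length(rows)) do.call(rbind, rows) else NULL
  report <- NULL
  if (!is.null(stats) && !is.null(cohort)) {
    if (length(unique(cohort$group)) < 2L)
      message("single-group study: group contrasts skipped")
    report <- run_study_stats(cohort, stats)
  }
  list(cohort = cohort, report = report, failures = failures,
       results = results)
}

#' Write a cohort table or stats report to CSV
#' @param x a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#' @param path CSV path with the cohort table schema.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
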