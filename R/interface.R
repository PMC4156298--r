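# Workflow drivers tying the stages together: fingerprint a pose
# ensemble end to end, and run kinetics fits with fold-change and
# accounting reports.  Outputs are plain TSV (plus an optional JSON
# mirror) and are byte-identical given identical inputs and parameters.

#' Run the fingerprint workflow on a receptor and pose ensemble
#'
#' Reads (or accepts) a receptor and docked poses, computes per-pose
#' nine-bit fingerprints, averages them, clusters the poses by RMSD and
#' extracts binding-site residues.  Writes to `outDir`:
#' `per_pose_sift.tsv` (long format), `averaged_sift.tsv` (amino acid x
#' nine bits, two decimals), `binding_site.txt`, `clusters.tsv`, and
#' `run_config.json` recording the parameters used (for provenance).
#'
#' @param receptor path to a PDB file or a [TypedStructure-class].
#' @param posePaths path(s) to PDBQT pose files, or a list of
#'   [LigandPose-class] objects.
#' @param outDir output directory (created if needed).
#' @param params an [InteractionParams-class].
#' @param rmsdCutoff pose-clustering RMSD cutoff (A).
#' @param siteThreshold `any`-bit frequency threshold for binding-site
#'   membership.
#' @param json also write `results.json` with the full results.
#' @return invisibly, a list with `sifts`, `averaged`, `clusters`,
#'   `site`.
#' @export
runSIFt <- function(receptor, posePaths, outDir,
                    params = interactionParams(), rmsdCutoff = 1.0,
                    siteThreshold = 0.3, json = FALSE) {
  if (is.character(receptor)) receptor <- readPDB(receptor)
  if (!is(receptor, "TypedStructure"))
    stop("receptor must be a PDB path or a TypedStructure")
  if (is.character(posePaths)) {
    posesList <- do.call(c, lapply(posePaths, readPDBQT))
  } else {
    posesList <- posePaths
  }
  if (!length(posesList))
    stop("no poses found; supply at least one PDBQT file or LigandPose")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  sifts <- lapply(posesList, computeSIFt, receptor = receptor,
                  params = params)
  avg <- averageSIFt(sifts)
  clusters <- clusterPoses(posesList, clusterParams(rmsdCutoff))
  site <- bindingSiteResidues(avg, siteThreshold)

  longDf <- do.call(rbind, lapply(sifts, as.data.frame))
  utils::write.table(longDf, file.path(outDir, "per_pose_sift.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeAveragedSIFt(avg, file.path(outDir, "averaged_sift.tsv"))
  writeLines(site, file.path(outDir, "binding_site.txt"))
  clDf <- do.call(rbind, lapply(seq_along(clusters), function(i)
    data.frame(cluster = i, representative = clusters[[i]]$representative,
               size = length(clusters[[i]]$members),
               members = paste(clusters[[i]]$members, collapse = ","))))
  utils::write.table(clDf, file.path(outDir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_poses = length(posesList), n_clusters = length(clusters),
         contact = params@contact, hbond_da = params@hbondDA,
         hbond_angle = params@hbondAngle,
         aromatic_centroid = params@aromaticCentroid,
         charged = params@charged, polar = params@polar,
         rmsd_cutoff = rmsdCutoff, site_threshold = siteThreshold),
    file.path(outDir, "run_config.json"), auto_unbox = TRUE, digits = NA)
  if (json) {
    jsonlite::write_json(
      list(averaged = as.data.frame(avg), binding_site = site,
           clusters = clDf, per_pose = longDf),
      file.path(outDir, "results.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(sifts = sifts, averaged = avg, clusters = clusters,
                 site = site))
}

fitRow <- function(name, fit) {
  if (!fit@converged) {
    return(data.frame(enzyme = name, kcat = NA, kcat_se = NA, Km = NA,
                      Km_se = NA, kcat_over_Km = NA, kcat_over_Km_se = NA,
                      h = NA, converged = FALSE))
  }
  data.frame(
    enzyme = name, kcat = fit@kcat, kcat_se = fit@kcatSe,
    Km = fit@estimates[["Km"]], Km_se = fit@se[["Km"]],
    kcat_over_Km = fit@kcatOverKm, kcat_over_Km_se = fit@kcatOverKmSe,
    h = fit@estimates[["h"]], converged = TRUE)
}

#' Run the kinetics workflow: fits, fold changes and accounting tables
#'
#' Fits the Hill equation to each dataset, then reports ratios for the
#' designated (mutant, reference) pairs.  Optionally appends
#' relative-activity and purification summaries.  Writes to `outDir`:
#' `fits.tsv` (kcat / Km / kcat/Km with standard errors per enzyme),
#' `fold_changes.tsv`, and when inputs are supplied
#' `relative_activity.tsv` and `purification.tsv`.  Non-converged fits
#' are reported with `converged = FALSE` and excluded from fold changes;
#' the run continues.
#'
#' @param assays named list of data.frames (or file paths readable by
#'   [readAssayTable()]) with saturation data.
#' @param enzymeConc enzyme concentration in uM: a single value or a
#'   vector named after the assays.
#' @param pairs list of `c(numerator, denominator)` assay-name pairs for
#'   fold changes (e.g. `list(c("Y120P", "WT"))`).
#' @param outDir output directory.
#' @param fixH optional fixed Hill coefficient passed to [fitHill()].
#' @param activity optional list with `table` (see [relativeActivity()])
#'   and optionally `reference` / `by`.
#' @param purification optional list with `steps` and optionally
#'   `yieldRef` / `foldRef` (see [purificationSummary()]).
#' @param json also write `results.json`.
#' @return invisibly, a list with `fits` (named list of
#'   [KineticFit-class]) and `foldChanges` (data.frame).
#' @export
runKinetics <- function(assays, enzymeConc, pairs = list(), outDir,
                        fixH = NULL, activity = NULL, purification = NULL,
                        json = FALSE) {
  if (missing(enzymeConc))
    stop("enzymeConc is required (uM); kcat = Vmax / enzymeConc")
  if (is.null(names(assays)) || any(!nzchar(names(assays))))
    stop("assays must be a named list")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ec <- function(nm) {
    if (length(enzymeConc) == 1L && is.null(names(enzymeConc)))
      return(enzymeConc)
    if (!nm %in% names(enzymeConc))
      stop("no enzymeConc entry for assay '", nm, "'")
    enzymeConc[[nm]]
  }
  fits <- lapply(names(assays), function(nm) {
    d <- assays[[nm]]
    if (is.character(d)) d <- readAssayTable(d)
    fitHill(d, enzymeConc = ec(nm), fixH = fixH)
  })
  names(fits) <- names(assays)

  fitDf <- do.call(rbind, Map(fitRow, names(fits), fits))
  utils::write.table(fitDf, file.path(outDir, "fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  fcDf <- data.frame(numerator = character(0), denominator = character(0),
                     kcat_ratio = numeric(0), Km_ratio = numeric(0),
                     kcat_over_Km_ratio = numeric(0))
  for (p in pairs) {
    a <- fits[[p[1L]]]
    b <- fits[[p[2L]]]
    if (is.null(a) || is.null(b))
      stop("fold-change pair refers to unknown assay: ",
           paste(p, collapse = " / "))
    if (!a@converged || !b@converged) {
      warning("skipping fold change ", p[1L], "/", p[2L],
              ": non-converged fit")
      next
    }
    fc <- foldChange(a, b)
    fcDf <- rbind(fcDf, data.frame(
      numerator = p[1L], denominator = p[2L],
      kcat_ratio = fc[["kcat"]], Km_ratio = fc[["Km"]],
      kcat_over_Km_ratio = fc[["kcat_over_Km"]]))
  }
  utils::write.table(fcDf, file.path(outDir, "fold_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  relDf <- NULL
  if (!is.null(activity)) {
    relDf <- relativeActivity(activity$table,
                              reference = activity$reference %||% "Control",
                              by = activity$by)
    utils::write.table(relDf, file.path(outDir, "relative_activity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  purDf <- NULL
  if (!is.null(purification)) {
    purDf <- purificationSummary(purification$steps,
                                 yieldRef = purification$yieldRef,
                                 foldRef = purification$foldRef)
    utils::write.table(purDf, file.path(outDir, "purification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (json) {
    jsonlite::write_json(
      list(fits = fitDf, fold_changes = fcDf, relative_activity = relDf,
           purification = purDf),
      file.path(outDir, "results.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(fits = fits, foldChanges = fcDf))
}
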