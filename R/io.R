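#' @include AllClasses.R pipeline.R
NULL

#' Write / read a VolumeImage as NIfTI-1
#'
#' Volumes are written RAS-oriented with the voxel spacing in the header
#' (`.nii` or `.nii.gz` from the file name). Reading restores values and
#' spacing; the patch origin is carried in the qform offset.
#'
#' @param vol a [VolumeImage-class].
#' @param path output file path.
#' @return `writeVolume()` the path, invisibly; `readVolume()` a
#'   [VolumeImage-class].
#' @export
writeVolume <- function(vol, path) {
    stopifnot(is(vol, "VolumeImage"))
    im <- RNifti::asNifti(vol@values)
    RNifti::pixdim(im) <- vol@spacing
    aff <- diag(c(vol@spacing, 1))
    aff[1:3, 4] <- vol@origin
    im <- RNifti::`qform<-`(im, structure(aff, code = 2L))
    RNifti::writeNifti(im, path)
    invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
    im <- RNifti::readNifti(path)
    aff <- RNifti::xform(im)
    volumeImage(array(as.numeric(im), dim = dim(im)),
                RNifti::pixdim(im)[1:3], aff[1:3, 4])
}

#' Write / read a FeatureTable as CSV
#'
#' Writes the documented pair of files: `feature_table_wide.csv` (one row
#' per protocol x material, the 93 feature columns in fixed order) and
#' `feature_table_long.csv` (`protocol_id`, `material_label`, `feature_name`,
#' `family`, `value`, `degenerate_flag`), plus `provenance.json` with the
#' settings, seed and settings hash. `readFeatureTable()` reconstructs the
#' [FeatureTable-class] from a directory written this way.
#'
#' @param ft a [FeatureTable-class].
#' @param dir output directory (created if needed).
#' @return `writeFeatureTable()` the directory, invisibly.
#' @export
writeFeatureTable <- function(ft, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    v <- featureValues(ft)
    cd <- as.data.frame(SummarizedExperiment::colData(ft))
    wide <- cbind(cd, as.data.frame(t(v)))
    rownames(wide) <- NULL
    write.csv(wide, file.path(dir, "feature_table_wide.csv"),
              row.names = FALSE)
    fl <- degenerateFlags(ft)
    long <- data.frame(
        protocol_id = rep(cd$protocol_id, each = nrow(v)),
        material_label = rep(cd$material_label, each = nrow(v)),
        feature_name = rep(rownames(v), times = ncol(v)),
        family = rep(featureFamilies93(), times = ncol(v)),
        value = as.numeric(v),
        degenerate_flag = as.logical(fl))
    write.csv(long, file.path(dir, "feature_table_long.csv"),
              row.names = FALSE)
    md <- S4Vectors::metadata(ft)
    st <- md$settings
    jsonlite::write_json(list(
        seed = md$seed, settings_hash = md$settings_hash,
        settings = list(binWidth = st@binWidth,
                        glcmDistance = st@glcmDistance,
                        gldmAlpha = st@gldmAlpha,
                        gldmDistance = st@gldmDistance,
                        ngtdmDistance = st@ngtdmDistance,
                        dimensionality = st@dimensionality)),
        file.path(dir, "provenance.json"), auto_unbox = TRUE)
    invisible(dir)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(dir) {
    wide <- read.csv(file.path(dir, "feature_table_wide.csv"),
                     check.names = FALSE)
    long <- read.csv(file.path(dir, "feature_table_long.csv"))
    prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                                simplifyVector = TRUE)
    feats <- featureNames93()
    vals <- t(as.matrix(wide[, feats]))
    fl <- matrix(long$degenerate_flag, nrow = length(feats))
    rownames(vals) <- rownames(fl) <- feats
    st <- prov$settings
    settings <- extractionSettings(binWidth = st$binWidth,
        glcmDistance = st$glcmDistance, gldmAlpha = st$gldmAlpha,
        gldmDistance = st$gldmDistance, ngtdmDistance = st$ngtdmDistance,
        dimensionality = st$dimensionality)
    featureTable(vals, fl,
                 wide[, c("protocol_id", "material_label", "material_name")],
                 settings, prov$seed)
}

summaryToList <- function(summary) {
    list(factor_reliability = summary@factorReliability,
         factor_variability = summary@factorVariability,
         material_variability = summary@materialVariability,
         pooled = summary@pooled, meta = summary@meta)
}

#' Write the study report
#'
#' Emits the machine-readable `summary.json` (full summary plus provenance),
#' the three CSV table analogs (per-factor reliability, per-factor
#' variability, per-material variability) and the feature table CSVs.
#'
#' @param summary a [RobustnessSummary-class].
#' @param ft the [FeatureTable-class] the summary was computed from.
#' @param outdir output directory.
#' @return the output directory, invisibly.
#' @export
writeReport <- function(summary, ft, outdir) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    jsonlite::write_json(summaryToList(summary),
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(summary@factorReliability,
              file.path(outdir, "table2_reliability.csv"), row.names = FALSE)
    write.csv(summary@factorVariability,
              file.path(outdir, "table3_variability_factor.csv"),
              row.names = FALSE)
    write.csv(summary@materialVariability,
              file.path(outdir, "table4_variability_material.csv"),
              row.names = FALSE)
    writeFeatureTable(ft, outdir)
    invisible(outdir)
}

#' Read back a written report
#'
#' @param outdir directory written by [writeReport()].
#' @return list with elements `summary` (parsed JSON) and the three tables.
#' @export
readReport <- function(outdir) {
    list(summary = jsonlite::read_json(file.path(outdir, "summary.json"),
                                       simplifyVector = TRUE),
         reliability = read.csv(file.path(outdir, "table2_reliability.csv")),
         variability_factor = read.csv(
             file.path(outdir, "table3_variability_factor.csv")),
         variability_material = read.csv(
             file.path(outdir, "table4_variability_material.csv")))
}

#' Read a study configuration from YAML
#'
#' Reads a YAML file with optional blocks `layout` (insert_diameter_mm,
#' fine_spacing_mm, fov_mm, background_hu, slab_mm), `materials` (rows
#' overriding the default material table by label), `extraction` (bin_width,
#' glcm_distance, gldm_alpha, gldm_distance, ngtdm_distance, dimensionality),
#' `physics` (any element of [defaultPhysics()]), `roi`
#' (diameter_px, n_layers) and `seed`. Missing entries fall back to package
#' defaults.
#'
#' @param path YAML file path.
#' @return list with `config` (a [StudyConfig-class]) and `seed`.
#' @export
readStudyConfig <- function(path) {
    y <- yaml::read_yaml(path)
    mats <- materialTable()
    if (!is.null(y$materials)) {
        for (ov in y$materials) {
            i <- match(ov$label, mats$label)
            if (is.na(i)) stop("unknown material label in config: ", ov$label)
            for (fld in intersect(names(ov), names(mats)))
                mats[i, fld] <- ov[[fld]]
        }
    }
    lay <- y$layout
    layout <- buildDefaultLayout(
        materials = mats,
        insertDiameter = lay$insert_diameter_mm %||% 32,
        fineSpacing = lay$fine_spacing_mm %||% 0.25,
        fov = lay$fov_mm %||% 400,
        backgroundHU = lay$background_hu %||% -800,
        slabThickness = lay$slab_mm %||% 32)
    ex <- y$extraction
    settings <- extractionSettings(
        binWidth = ex$bin_width %||% 25,
        glcmDistance = ex$glcm_distance %||% 1L,
        gldmAlpha = ex$gldm_alpha %||% 0L,
        gldmDistance = ex$gldm_distance %||% 1L,
        ngtdmDistance = ex$ngtdm_distance %||% 1L,
        dimensionality = ex$dimensionality %||% "threeD")
    physics <- utils::modifyList(defaultPhysics(), y$physics %||% list())
    roi <- y$roi
    config <- studyConfig(layout = layout, settings = settings,
                          physics = physics,
                          roiDiameterPx = roi$diameter_px %||% 35,
                          roiLayers = roi$n_layers %||% 25L)
    list(config = config, seed = as.integer(y$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stacked-bar plot of robustness bin percentages
#'
#' Reproduces the style of the percent-robust-features bar charts: one bar
#' per influencing factor (or material), stacked by interpretation bin.
#' Requires ggplot2.
#'
#' @param summary a [RobustnessSummary-class].
#' @param metric `"ICC"`, `"CCC"`, `"CV"` or `"QCD"`.
#' @param by `"factor"` or `"material"`.
#' @return a ggplot object.
#' @export
plotRobustness <- function(summary, metric = "ICC", by = "factor") {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("ggplot2 is required for plotting")
    metric <- toupper(metric)
    tab <- if (by == "factor") {
        if (metric %in% c("ICC", "CCC")) summary@factorReliability
        else summary@factorVariability
    } else summary@materialVariability
    tab <- tab[tab$metric == metric, ]
    bins <- robustnessBins(
        if (metric %in% c("ICC", "CCC")) "reliability" else "variability")
    pctCols <- paste0("pct_", bins)
    xvar <- if (by == "factor") "factor" else "material_name"
    longd <- do.call(rbind, lapply(bins, function(b) data.frame(
        x = tab[[xvar]], bin = b, pct = tab[[paste0("pct_", b)]])))
    longd$bin <- factor(longd$bin, levels = rev(bins))
    ggplot2::ggplot(longd, ggplot2::aes(x = .data$x, y = .data$pct,
                                        fill = .data$bin)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = NULL, y = "% of 93 features", fill = metric) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
}
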