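#' @include acquisition.R roi.R extract.R stats.R
NULL

#' Assemble a study configuration
#'
#' @param layout a [PhantomLayout-class] (default [buildDefaultLayout()]).
#' @param protocols protocol suite (default [defaultProtocolSuite()]).
#' @param settings an [ExtractionSettings-class].
#' @param physics surrogate parameters (default [defaultPhysics()]).
#' @param roiDiameterPx ROI disk diameter in pixels (default 35).
#' @param roiLayers ROI cylinder slices (default 25).
#' @return a [StudyConfig-class].
#' @export
studyConfig <- function(layout = buildDefaultLayout(),
                        protocols = defaultProtocolSuite(),
                        settings = extractionSettings(),
                        physics = defaultPhysics(),
                        roiDiameterPx = 35, roiLayers = 25L) {
    validateProtocolSuite(protocols)
    new("StudyConfig", layout = layout, protocols = protocols,
        settings = settings, physics = physics,
        roiDiameterPx = roiDiameterPx, roiLayers = as.integer(roiLayers))
}

# FeatureTable constructor
featureTable <- function(values, degenerate, colData, settings, seed) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = values, degenerate = degenerate),
        rowData = S4Vectors::DataFrame(family = featureFamilies93(),
                                       row.names = featureNames93()),
        colData = S4Vectors::DataFrame(colData))
    S4Vectors::metadata(se) <- list(
        settings = settings, seed = as.integer(seed),
        settings_hash = settingsHash(list(settings, seed)))
    new("FeatureTable", se)
}

#' FeatureTable accessors
#'
#' @param x a [FeatureTable-class].
#' @return `featureValues()` the 93 x N numeric matrix; `degenerateFlags()`
#'   the logical flag matrix; `protocolIds()` / `materialLabels()` the column
#'   annotations.
#' @name FeatureTable-accessors
NULL

#' @rdname FeatureTable-accessors
#' @export
featureValues <- function(x) SummarizedExperiment::assay(x, "values")

#' @rdname FeatureTable-accessors
#' @export
degenerateFlags <- function(x) SummarizedExperiment::assay(x, "degenerate")

#' @rdname FeatureTable-accessors
#' @export
protocolIds <- function(x) SummarizedExperiment::colData(x)$protocol_id

#' @rdname FeatureTable-accessors
#' @export
materialLabels <- function(x) SummarizedExperiment::colData(x)$material_label

# stable per-protocol seed salt: position in the canonical suite, so that
# running a subset of the suite reproduces the full run's columns exactly
protocolSalt <- function(id, rowIndex) {
    i <- match(id, c("reference", "reposition", "high_pitch", "kvp140",
                     "slice04", "dose05", "dose10", "dose30", "dose50",
                     "qir0", "qir2", "qr44", "qr48"))
    if (is.na(i)) i <- 20L + rowIndex
    i
}

# transform of a protocol scan (reposition uses the configured transform)
protocolTransform <- function(protocolId, physics) {
    if (protocolId == "reposition")
        rigidTransform(physics$reposition$translation,
                       physics$reposition$rotationZ)
    else rigidTransform()
}

#' Run the full simulated study
#'
#' Generates the ground-truth phantom once per master seed, simulates every
#' protocol of the suite (each insert patch degraded with its own derived
#' noise seed), builds the pixel-defined cylindrical ROIs and extracts the
#' 93-feature vector for every (protocol, material) pair. Fully
#' deterministic: the same configuration and master seed yield an identical
#' table.
#'
#' @param config a [StudyConfig-class].
#' @param seed integer master seed.
#' @return a [FeatureTable-class] with one column per (protocol, material).
#' @export
runSuite <- function(config, seed = 1L) {
    validObject(config)
    layout <- config@layout
    protocols <- config@protocols
    physics <- config@physics
    settings <- config@settings
    mats <- layout@materials
    gt <- tryCatch(generateGroundTruth(layout, deriveSeed(seed, 1)),
                   error = function(e) stop("ground-truth stage: ",
                                            conditionMessage(e)))
    dPx <- config@roiDiameterPx
    nLay <- config@roiLayers
    halfWin <- as.integer(ceiling(dPx / 2) + 6L)
    nCol <- nrow(protocols) * nrow(mats)
    vals <- matrix(NA_real_, 93L, nCol)
    flags <- matrix(FALSE, 93L, nCol)
    cd <- data.frame(protocol_id = character(nCol),
                     material_label = integer(nCol),
                     material_name = character(nCol),
                     stringsAsFactors = FALSE)
    avgCache <- list()
    col <- 0L
    for (pi in seq_len(nrow(protocols))) {
        p <- protocols[pi, ]
        transform <- protocolTransform(p$id, physics)
        s <- pixelSpacing(p)
        zg <- protocolZGrid(gt@patches[[1]], p)
        zVals <- zg$z + transform@translation[3]
        if (nLay > zg$nz)
            stop("roi stage: nLayers exceeds the ", p$id, " slab")
        gridKey <- paste0("f", paste(c(floor(s / layout@fineSpacing),
                          floor(p$slice_thickness / layout@fineSpacing)),
                          collapse = "_"))
        for (r in seq_len(nrow(mats))) {
            lab <- as.character(mats$label[r])
            ck <- paste0(lab, ".", gridKey)
            if (is.null(avgCache[[ck]]))
                avgCache[[ck]] <- tryCatch(
                    blockAverageVolume(gt@patches[[lab]], p),
                    error = function(e) stop("resampling stage: ",
                                             conditionMessage(e)))
            avg <- avgCache[[ck]]
            tc <- applyTransform(transform,
                                 matrix(layout@insertCenters[r, ], 1, 3))
            ci <- (tc[1] + p$fov / 2) / s + 0.5
            cj <- (tc[2] + p$fov / 2) / s + 0.5
            iIdx <- seq(round(ci) - halfWin, round(ci) + halfWin)
            jIdx <- seq(round(cj) - halfWin, round(cj) + halfWin)
            sim <- degradeAveraged(avg, p, transform,
                                   deriveSeed(seed, 100L * protocolSalt(p$id, pi) +
                                              mats$label[r]),
                                   physics, mats$kvp_factor[r], iIdx, jIdx,
                                   zVals)
            kc <- which.min(abs(zVals - tc[3]))
            kIdx <- kc + seq(-(nLay - 1L) %/% 2L, nLay %/% 2L)
            if (min(kIdx) < 1L || max(kIdx) > zg$nz)
                stop("roi stage: ROI slices outside the slab for material ",
                     lab)
            disk <- diskMembership(seq_along(iIdx), seq_along(jIdx),
                                   ci - iIdx[1] + 1, cj - jIdx[1] + 1, dPx)
            mask <- array(FALSE, dim = dim(sim@values))
            for (k in kIdx) mask[, , k] <- disk
            fv <- tryCatch(extractFeatureVector(sim, mask, settings),
                           error = function(e) stop("extraction stage: ",
                                                    conditionMessage(e)))
            col <- col + 1L
            vals[, col] <- as.numeric(fv)
            flags[, col] <- attr(fv, "degenerate")
            cd$protocol_id[col] <- p$id
            cd$material_label[col] <- mats$label[r]
            cd$material_name[col] <- mats$name[r]
        }
    }
    rownames(vals) <- rownames(flags) <- featureNames93()
    featureTable(vals, flags, cd, settings, seed)
}

# n x k matrix (materials x protocols) of one feature
featureDesign <- function(ft, feature, protocolIdsWanted) {
    v <- featureValues(ft)
    pid <- protocolIds(ft)
    lab <- materialLabels(ft)
    labs <- sort(unique(lab))
    out <- sapply(protocolIdsWanted, function(id) {
        cols <- which(pid == id)
        if (!length(cols)) stop("protocol ", id, " missing from the table")
        v[feature, cols[match(labs, lab[cols])]]
    })
    rownames(out) <- labs
    out
}

#' Per-feature reproducibility between two protocols
#'
#' For each of the 93 features, builds the materials x 2 paired design
#' (reference vs comparison protocol) and computes ICC(A,1) and Lin's CCC.
#' Materials with non-finite values in either protocol are dropped and
#' counted.
#'
#' @param ft a [FeatureTable-class].
#' @param reference reference protocol id.
#' @param comparison comparison protocol id.
#' @return data.frame with one row per feature: `feature`, `family`, `icc`,
#'   `ccc`, `n`, `k`, the ANOVA mean squares, `degenerate`, `n_dropped`.
#' @export
reproducibilityPerFactor <- function(ft, reference = "reference", comparison) {
    feats <- featureNames93()
    res <- lapply(feats, function(f) {
        m <- featureDesign(ft, f, c(reference, comparison))
        ok <- is.finite(m[, 1]) & is.finite(m[, 2])
        dropped <- sum(!ok)
        m <- m[ok, , drop = FALSE]
        if (nrow(m) < 2)
            return(data.frame(feature = f, icc = NA_real_, ccc = NA_real_,
                              n = nrow(m), k = 2L, ms_rows = NA_real_,
                              ms_cols = NA_real_, ms_err = NA_real_,
                              degenerate = TRUE, n_dropped = dropped))
        icc <- iccAbsoluteAgreement(m)
        ccc <- linCCC(m[, 1], m[, 2])
        data.frame(feature = f, icc = icc$icc, ccc = as.numeric(ccc),
                   n = icc$n, k = icc$k, ms_rows = icc$ms_rows,
                   ms_cols = icc$ms_cols, ms_err = icc$ms_err,
                   degenerate = icc$degenerate, n_dropped = dropped)
    })
    out <- do.call(rbind, res)
    out$family <- featureFamilies93()
    out[, c("feature", "family", setdiff(names(out), c("feature", "family")))]
}

#' Per-feature variability between two protocols
#'
#' CV and QCD of the {reference, comparison} value pair, computed per
#' material and aggregated over materials (mean by default). Undefined pairs
#' (zero mean or zero quartile sum) are excluded with their counts reported.
#' The full per-material pair values are attached as attribute `"pairs"` for
#' pooled summary blocks.
#'
#' @inheritParams reproducibilityPerFactor
#' @param aggregate `"mean"` or `"median"` over materials.
#' @return data.frame with one row per feature: `feature`, `family`, `cv`,
#'   `qcd`, `n_materials`, `n_undefined_cv`, `n_undefined_qcd`.
#' @export
variabilityPerFactor <- function(ft, reference = "reference", comparison,
                                 aggregate = c("mean", "median")) {
    aggregate <- match.arg(aggregate)
    aggFun <- if (aggregate == "mean") {
        function(x) mean(x, na.rm = TRUE)
    } else function(x) median(x, na.rm = TRUE)
    feats <- featureNames93()
    pairRows <- list()
    res <- lapply(feats, function(f) {
        m <- featureDesign(ft, f, c(reference, comparison))
        cvs <- apply(m, 1, coefficientOfVariation)
        qcds <- apply(m, 1, quartileCoefficientOfDispersion)
        pairRows[[f]] <<- data.frame(feature = f,
            material_label = as.integer(rownames(m)), cv = cvs, qcd = qcds,
            row.names = NULL)
        data.frame(feature = f,
                   cv = if (all(is.na(cvs))) NA_real_ else aggFun(cvs),
                   qcd = if (all(is.na(qcds))) NA_real_ else aggFun(qcds),
                   n_materials = nrow(m),
                   n_undefined_cv = sum(is.na(cvs)),
                   n_undefined_qcd = sum(is.na(qcds)))
    })
    out <- do.call(rbind, res)
    out$family <- featureFamilies93()
    out <- out[, c("feature", "family",
                   setdiff(names(out), c("feature", "family")))]
    attr(out, "pairs") <- do.call(rbind, pairRows)
    out
}

#' Per-feature variability of one material across all protocols
#'
#' CV and QCD of each feature over its values under every protocol of the
#' table (all 13 in a default run).
#'
#' @param ft a [FeatureTable-class].
#' @param label material label.
#' @return data.frame with one row per feature: `feature`, `family`, `cv`,
#'   `qcd`, `n` (number of protocol values used).
#' @export
variabilityPerMaterial <- function(ft, label) {
    pid <- unique(protocolIds(ft))
    lab <- materialLabels(ft)
    cols <- which(lab == as.integer(label))
    if (!length(cols)) stop("material ", label, " not present")
    have <- protocolIds(ft)[cols]
    missing <- setdiff(pid, have)
    if (length(missing))
        stop("material ", label, " missing protocol(s): ",
             paste(missing, collapse = ", "))
    v <- featureValues(ft)[, cols[match(pid, have)], drop = FALSE]
    data.frame(feature = featureNames93(), family = featureFamilies93(),
               cv = apply(v, 1, coefficientOfVariation),
               qcd = apply(v, 1, quartileCoefficientOfDispersion),
               n = length(pid), row.names = NULL)
}

#' Factor comparisons of a protocol suite
#'
#' @param protocols protocol suite data.frame.
#' @return data.frame mapping each influencing factor (every non-reference
#'   protocol) to the comparison protocol id.
#' @export
factorComparisons <- function(protocols = defaultProtocolSuite()) {
    p <- protocols[protocols$id != "reference", ]
    data.frame(factor = p$factor_label, comparison = p$id,
               stringsAsFactors = FALSE)
}

binPercentages <- function(values, metric) {
    bins <- robustnessBins(metric)
    cls <- factor(classifyRobustness(values, metric), levels = bins)
    pct <- round(100 * as.numeric(table(cls)) / length(values), 1)
    setNames(as.list(pct), paste0("pct_", bins))
}

summaryStats <- function(x) {
    x <- x[is.finite(x)]
    list(mean = mean(x), sd = sd(x), median = median(x),
         q1 = quantile(x, 0.25, names = FALSE, type = 7),
         q3 = quantile(x, 0.75, names = FALSE, type = 7))
}

#' Summarize a study into robustness tables
#'
#' Computes, for every influencing factor of the suite, per-feature ICC/CCC
#' (reference vs comparison) and aggregated CV/QCD; for every material,
#' per-feature CV/QCD across all protocols; bins each value with
#' [classifyRobustness()]; and reports mean +/- SD, median (IQR) and the
#' percentage of the 93 features per bin (denominator always 93, undefined
#' values form an explicit bin). Percentages use one decimal place. The
#' mean/SD/median blocks of the per-factor variability rows come from the
#' pooled feature x material pair list; bin percentages come from the
#' per-feature aggregated values.
#'
#' @param ft a [FeatureTable-class] covering the full suite.
#' @param aggregate over-materials aggregation of per-factor CV/QCD.
#' @return a [RobustnessSummary-class].
#' @export
summarizeRobustness <- function(ft, aggregate = "mean") {
    pid <- unique(protocolIds(ft))
    ds <- defaultProtocolSuite()
    comps <- setdiff(pid, "reference")
    protoRows <- data.frame(
        factor = ifelse(comps %in% ds$id,
                        ds$factor_label[match(comps, ds$id)], comps),
        comparison = comps, stringsAsFactors = FALSE)
    relRows <- list()
    varRows <- list()
    pooledICC <- c(); pooledCCC <- c(); pooledCV <- c(); pooledQCD <- c()
    for (r in seq_len(nrow(protoRows))) {
        fac <- protoRows$factor[r]
        comp <- protoRows$comparison[r]
        rel <- reproducibilityPerFactor(ft, "reference", comp)
        for (metric in c("icc", "ccc")) {
            v <- rel[[metric]]
            st <- summaryStats(v)
            relRows[[paste(fac, metric)]] <- data.frame(
                factor = fac, comparison = comp, metric = toupper(metric),
                mean = st$mean, sd = st$sd, median = st$median, q1 = st$q1,
                q3 = st$q3, as.data.frame(binPercentages(v, "reliability")),
                stringsAsFactors = FALSE)
        }
        pooledICC <- c(pooledICC, rel$icc)
        pooledCCC <- c(pooledCCC, rel$ccc)
        vv <- variabilityPerFactor(ft, "reference", comp,
                                   aggregate = aggregate)
        pairs <- attr(vv, "pairs")
        for (metric in c("cv", "qcd")) {
            pooled <- pairs[[metric]]
            st <- summaryStats(pooled)
            varRows[[paste(fac, metric)]] <- data.frame(
                factor = fac, comparison = comp, metric = toupper(metric),
                mean = st$mean, sd = st$sd, median = st$median, q1 = st$q1,
                q3 = st$q3,
                as.data.frame(binPercentages(vv[[metric]], "variability")),
                n_undefined = sum(is.na(pooled)), stringsAsFactors = FALSE)
        }
        pooledCV <- c(pooledCV, pairs$cv)
        pooledQCD <- c(pooledQCD, pairs$qcd)
    }
    labs <- sort(unique(materialLabels(ft)))
    names_ <- SummarizedExperiment::colData(ft)
    matRows <- list()
    for (lab in labs) {
        mv <- variabilityPerMaterial(ft, lab)
        nm <- names_$material_name[match(lab, names_$material_label)]
        for (metric in c("cv", "qcd")) {
            v <- mv[[metric]]
            st <- summaryStats(v)
            matRows[[paste(lab, metric)]] <- data.frame(
                material_label = lab, material_name = nm,
                metric = toupper(metric), mean = st$mean, sd = st$sd,
                median = st$median, q1 = st$q1, q3 = st$q3,
                as.data.frame(binPercentages(v, "variability")),
                n_undefined = sum(is.na(v)), stringsAsFactors = FALSE)
        }
    }
    pooled <- list(
        icc = summaryStats(pooledICC), ccc = summaryStats(pooledCCC),
        cv = summaryStats(pooledCV), qcd = summaryStats(pooledQCD))
    md <- S4Vectors::metadata(ft)
    new("RobustnessSummary",
        factorReliability = do.call(rbind, c(relRows,
                                             list(make.row.names = FALSE))),
        factorVariability = do.call(rbind, c(varRows,
                                             list(make.row.names = FALSE))),
        materialVariability = do.call(rbind, c(matRows,
                                               list(make.row.names = FALSE))),
        pooled = pooled,
        meta = list(n_features = 93L, aggregate = aggregate,
                    seed = md$seed, settings_hash = md$settings_hash))
}

#' RobustnessSummary accessors
#'
#' @param x a [RobustnessSummary-class].
#' @return the corresponding summary data.frame or list.
#' @name RobustnessSummary-accessors
NULL

#' @rdname RobustnessSummary-accessors
#' @export
factorReliability <- function(x) x@factorReliability

#' @rdname RobustnessSummary-accessors
#' @export
factorVariability <- function(x) x@factorVariability

#' @rdname RobustnessSummary-accessors
#' @export
materialVariability <- function(x) x@materialVariability

#' @rdname RobustnessSummary-accessors
#' @export
pooledSummary <- function(x) x@pooled
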