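#' @include AllClasses.R
NULL

#' The 13-protocol acquisition/reconstruction suite
#'
#' Returns the full protocol matrix of the study design: a reference
#' abdomen-pelvis protocol and twelve one-factor-at-a-time variations
#' (reposition; high-pitch scan mode with reduced FOV; 140 kVp; 0.4 mm
#' slices; four reduced dose levels; quantum iterative reconstruction
#' strengths 0 and 2; kernels Qr44 and Qr48).
#'
#' @return data.frame with one row per protocol and columns `id`,
#'   `factor_label`, `scan_mode`, `kvp`, `mas`, `slice_thickness`,
#'   `matrix_size`, `fov`, `rotation_time`, `pitch`, `ctdivol`,
#'   `qir_level`, `kernel`. In-plane pixel spacing is `fov / matrix_size`.
#' @examples
#' suite <- defaultProtocolSuite()
#' nrow(suite)                       # 13
#' subset(suite, id == "high_pitch") # FOV 350 mm, pitch 3.2
#' @export
defaultProtocolSuite <- function() {
    p <- data.frame(
        id = c("reference", "reposition", "high_pitch", "kvp140", "slice04",
               "dose05", "dose10", "dose30", "dose50", "qir0", "qir2",
               "qr44", "qr48"),
        factor_label = c("Reference", "Reposition", "High-pitch scan",
                         "Tube voltage", "Slice thickness", "Dose 0.5 mGy",
                         "Dose 1.0 mGy", "Dose 3.0 mGy", "Dose 5.0 mGy",
                         "QIR level 0", "QIR level 2", "Kernel Qr44",
                         "Kernel Qr48"),
        scan_mode = c("standard", "standard", "high_pitch", rep("standard", 10)),
        kvp = c(120, 120, 120, 140, rep(120, 9)),
        mas = c(127, 127, 127, 87, 127, 6, 13, 38, 63, 127, 127, 127, 127),
        slice_thickness = c(1, 1, 1, 1, 0.4, rep(1, 8)),
        matrix_size = rep(512L, 13),
        fov = c(400, 400, 350, rep(400, 10)),
        rotation_time = c(0.5, 0.5, 0.25, rep(0.5, 10)),
        pitch = c(0.8, 0.8, 3.2, rep(0.8, 10)),
        ctdivol = c(10, 10, 10, 10, 10, 0.47, 1.03, 3.00, 4.98, 10, 10, 10, 10),
        qir_level = c(4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 0L, 2L, 4L, 4L),
        kernel = c(rep("Qr40", 11), "Qr44", "Qr48"),
        stringsAsFactors = FALSE)
    validateProtocolSuite(p)
    p
}

#' Validate a protocol suite table
#'
#' Checks the structural invariants of a protocol table: positive dose and
#' slice thickness, FOV 350 mm only in high-pitch mode, known kernels and
#' QIR levels.
#'
#' @param protocols data.frame as returned by [defaultProtocolSuite()].
#' @return the table, invisibly; errors on violation.
#' @export
validateProtocolSuite <- function(protocols) {
    stopifnot(is.data.frame(protocols), nrow(protocols) >= 1)
    need <- c("id", "scan_mode", "kvp", "mas", "slice_thickness", "matrix_size",
              "fov", "rotation_time", "pitch", "ctdivol", "qir_level", "kernel")
    if (!all(need %in% names(protocols)))
        stop("protocol table is missing columns: ",
             paste(setdiff(need, names(protocols)), collapse = ", "))
    if (anyDuplicated(protocols$id)) stop("protocol ids must be unique")
    if (any(protocols$ctdivol <= 0)) stop("ctdivol must be > 0")
    if (any(protocols$slice_thickness <= 0)) stop("slice_thickness must be > 0")
    if (any(protocols$fov == 350 & protocols$scan_mode != "high_pitch"))
        stop("FOV 350 mm is reserved for high-pitch mode")
    if (!all(protocols$scan_mode %in% c("standard", "high_pitch")))
        stop("unknown scan_mode")
    if (!all(protocols$kernel %in% c("Qr40", "Qr44", "Qr48")))
        stop("unknown kernel")
    if (!all(protocols$qir_level %in% 0:4)) stop("qir_level must be in 0..4")
    invisible(protocols)
}

#' Look up one protocol row by id
#'
#' @param protocols protocol suite data.frame.
#' @param id protocol id.
#' @return one-row data.frame.
#' @export
getProtocol <- function(protocols, id) {
    row <- protocols[protocols$id == id, , drop = FALSE]
    if (nrow(row) != 1L) stop("unknown protocol id: ", id)
    row
}

# In-plane pixel spacing of a protocol grid (mm)
pixelSpacing <- function(protocol) protocol$fov / protocol$matrix_size
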