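#' @include AllClasses.R
NULL

#' Material table of the 28-insert texture phantom
#'
#' The 28 insert materials (grains, seeds, woods, sponges, salts, water and
#' soils) with the texture parameters of their synthetic surrogates: mean
#' attenuation, marginal texture SD, spatial correlation length and texture
#' family. `kvp_factor` is the per-material contrast multiplier applied when
#' the tube voltage is 140 kVp (within +/- 3 percent of unity; exactly 1 for
#' water, whose attenuation defines the HU scale).
#'
#' The attenuation and texture values are declared surrogate parameters chosen
#' to span the HU and texture-scale range of the physical inserts; they are
#' not measurements.
#'
#' @return data.frame with columns `label`, `name`, `family`, `mean_hu`,
#'   `texture_sd`, `correlation_length`, `kvp_factor`.
#' @export
materialTable <- function() {
    m <- data.frame(
        label = 1:28,
        name = c("cat litter", "coix seed", "rice", "iodize-free salt",
                 "buckwheat", "flour", "soybean", "quinoa", "rosewood",
                 "chicken wing wood", "beechwood", "zebra wood", "basswood",
                 "mung bean", "mesoporous sponge", "millet",
                 "microporous sponge", "red bean", "sand", "nutritive soil",
                 "granulated sugar", "water", "iodized salt", "sago",
                 "chia seed", "oat", "coarse-pore sponge", "sawdust"),
        family = c("granular", "granular", "granular", "granular", "granular",
                   "homogeneous", "granular", "granular", "fibrous", "fibrous",
                   "fibrous", "fibrous", "fibrous", "granular", "porous",
                   "granular", "porous", "granular", "granular", "granular",
                   "granular", "homogeneous", "granular", "granular",
                   "granular", "granular", "porous", "fibrous"),
        mean_hu = c(250, -80, 120, 900, -150, -250, -350, 60, -300, -450,
                    -550, -400, -650, -250, -750, 20, -680, -200, 650, -450,
                    -100, 0, 950, -120, -300, -500, -600, -700),
        texture_sd = c(90, 110, 100, 130, 95, 25, 140, 85, 70, 80, 60, 90,
                       55, 120, 90, 90, 120, 115, 120, 100, 80, 3, 125, 105,
                       130, 110, 140, 65),
        correlation_length = c(1.5, 2.5, 1.8, 1.2, 2.2, 1.0, 3.0, 1.4, 1.2,
                               1.5, 1.3, 1.8, 1.6, 2.8, 1.5, 1.6, 0.8, 2.6,
                               1.0, 2.0, 1.2, 1.0, 1.2, 2.4, 1.6, 2.2, 3.5,
                               1.0),
        stringsAsFactors = FALSE)
    # fixed deterministic 140 kVp contrast factors within +/- 3 %
    m$kvp_factor <- round(1 + 0.03 * sin(m$label * 2.4), 4)
    m$kvp_factor[m$name == "water"] <- 1
    m
}

#' Build the default phantom layout
#'
#' Places the 28 material inserts on three concentric rings (radii 55, 105 and
#' 150 mm) inside a 400 mm FOV, snapped in-plane to the reference
#' reconstruction lattice (400/512 mm pixels) so that reference ROIs are
#' pixel-centred. Deterministic: two calls return identical layouts.
#'
#' @param materials material table (default [materialTable()]).
#' @param insertDiameter insert diameter in mm.
#' @param fineSpacing isotropic ground-truth grid spacing in mm.
#' @param fov field of view in mm.
#' @param backgroundHU HU of the supporting foam.
#' @param slabThickness longitudinal phantom extent in mm.
#' @return a [PhantomLayout-class].
#' @examples
#' layout <- buildDefaultLayout()
#' nrow(layoutMaterials(layout))  # 28
#' @export
buildDefaultLayout <- function(materials = materialTable(),
                               insertDiameter = 32, fineSpacing = 0.25,
                               fov = 400, backgroundHU = -800,
                               slabThickness = 32) {
    n <- nrow(materials)
    rings <- list(c(r = 55, k = 6, off = 0),
                  c(r = 105, k = 10, off = pi / 10),
                  c(r = 150, k = 12, off = 0))
    cen <- matrix(0, 0, 3)
    for (rg in rings) {
        ang <- rg[["off"]] + 2 * pi * (seq_len(rg[["k"]]) - 1) / rg[["k"]]
        cen <- rbind(cen, cbind(rg[["r"]] * cos(ang), rg[["r"]] * sin(ang), 0))
    }
    if (nrow(cen) < n) stop("ring layout supports at most ", nrow(cen), " inserts")
    cen <- cen[seq_len(n), , drop = FALSE]
    # snap in-plane to the reference lattice: pixel centres at
    # -fov/2 + (i - 0.5) * s
    s <- fov / 512
    snap <- function(x) {
        i <- round((x + fov / 2) / s + 0.5)
        -fov / 2 + (i - 0.5) * s
    }
    cen[, 1] <- snap(cen[, 1])
    cen[, 2] <- snap(cen[, 2])
    new("PhantomLayout", materials = materials, insertCenters = cen,
        insertDiameter = insertDiameter, fineSpacing = fineSpacing, fov = fov,
        backgroundHU = backgroundHU, slabThickness = slabThickness)
}
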