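# Cortical area sets: names, hemispheres, network labels, centroids and
# pairwise cortical distances. The default set covers 39 functionally
# localized visual / visually-associated areas spanning occipital, temporal,
# parietal, cingulate and frontal cortex; an expanded whole-cortex variant
# with 180 parcels per hemisphere is available for control analyses.

# Ordering within each network doubles as the planted functional-hierarchy
# coordinate used by the synthetic-data generator (occipito-temporal areas
# run V1 -> AT; fronto-parietal areas run posterior parietal -> frontal).
.ventral_area_names <- c(
  "V1", "V2", "V3", "hV4", "V3A", "V3B", "LO1", "LO2", "VO1", "VO2",
  "IPS0", "TO1", "TO2", "PHC1", "PHC2", "TOS", "EBA", "OFA", "LOC",
  "PPA", "FBA", "pSTS", "FFA", "AT"
)
.dorsal_area_names <- c(
  "IPS1", "IPS2", "IPS3", "IPS4", "SPL1", "FEF", "IFS",
  "IPS5", "antPPC", "latTemp",
  "IPL", "PreC", "latPPC", "medPPC", "RSC"
)

#' Construct an AreaSet
#'
#' @param names character area names (one hemisphere's worth).
#' @param network factor/character network label per area.
#' @param gradient numeric in `[0, 1]`: position of each area along its
#'   network's functional hierarchy (used by the simulator's topography).
#' @param centroid numeric `n x 3` matrix of right-hemisphere surface
#'   centroids in mm (left hemisphere is mirrored across x = 0).
#' @param hemispheres character vector, subset of `c("L", "R")`.
#' @param parcellation tag, e.g. `"functional-39"` or `"hcp-180"`.
#' @return an object of class `area_set`: a list with per-hemisphere
#'   replicated `name`, `hemisphere`, `network`, `gradient` vectors, an
#'   `n_total x 3` centroid matrix and an `n_total x n_total` cortical
#'   distance matrix (Euclidean between centroids; cross-hemisphere
#'   distances are defined but the analyses are within-hemisphere).
#' @export
area_set <- function(names, network, gradient, centroid,
                     hemispheres = c("L", "R"),
                     parcellation = "custom") {
  stopifnot(length(names) == length(network),
            length(names) == length(gradient),
            nrow(centroid) == length(names), ncol(centroid) == 3)
  hemispheres <- match.arg(hemispheres, c("L", "R"), several.ok = TRUE)
  nm <- hemi <- net <- grad <- character(0)
  grad <- numeric(0)
  cent <- NULL
  for (h in hemispheres) {
    nm <- c(nm, names)
    hemi <- c(hemi, rep(h, length(names)))
    net <- c(net, as.character(network))
    grad <- c(grad, gradient)
    ch <- centroid
    if (h == "L") ch[, 1] <- -ch[, 1]
    cent <- rbind(cent, ch)
  }
  rownames(cent) <- paste(nm, hemi, sep = "_")
  d <- as.matrix(stats::dist(cent))
  dimnames(d) <- list(rownames(cent), rownames(cent))
  structure(
    list(name = nm, hemisphere = hemi, network = net, gradient = grad,
         centroid = cent, distance = d, hemispheres = hemispheres,
         parcellation = parcellation),
    class = "area_set"
  )
}

#' @export
print.area_set <- function(x, ...) {
  cat(sprintf("AreaSet '%s': %d areas x %d hemisphere(s) (%d rows)\n",
              x$parcellation, length(unique(x$name)),
              length(x$hemispheres), length(x$name)))
  tb <- table(x$network[x$hemisphere == x$hemispheres[1]])
  cat("  networks:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Row indices of an area set belonging to one hemisphere
#' @param areas an `area_set`.
#' @param hemi `"L"` or `"R"`.
#' @return integer indices.
#' @export
area_hemi_idx <- function(areas, hemi) which(areas$hemisphere == hemi)

# Plausible right-hemisphere surface centroids (mm). The occipito-temporal
# areas run along a posterior-occipital -> anterior-temporal arc and the
# fronto-parietal areas along a posterior-parietal -> frontal arc, so that
# Euclidean centroid distance tracks position in the functional hierarchy.
.default_centroids <- function() {
  nv <- length(.ventral_area_names)
  gv <- seq(0, 1, length.out = nv)
  ventral <- cbind(
    x = 15 + 30 * gv,
    y = -95 + 70 * gv,
    z = -8 + 6 * sin(pi * gv)
  )
  nd <- length(.dorsal_area_names)
  gd <- seq(0, 1, length.out = nd)
  dorsal <- cbind(
    x = 24 + 8 * sin(pi * gd),
    y = -80 + 85 * gd,
    z = 48 + 8 * sin(pi * gd)
  )
  rbind(ventral, dorsal)
}

#' The default 39-area visual/attention area set
#'
#' Thirty-nine functionally localized areas across occipital, temporal,
#' parietal, cingulate and frontal cortex, grouped into an occipito-temporal
#' ("ventral") and a fronto-parietal ("dorsal") network, replicated over
#' both hemispheres.
#'
#' @param hemispheres subset of `c("L", "R")`.
#' @return an `area_set`.
#' @export
default_area_set <- function(hemispheres = c("L", "R")) {
  nv <- length(.ventral_area_names)
  nd <- length(.dorsal_area_names)
  area_set(
    names = c(.ventral_area_names, .dorsal_area_names),
    network = c(rep("occipito-temporal", nv), rep("fronto-parietal", nd)),
    gradient = c(seq(0, 1, length.out = nv), seq(0, 1, length.out = nd)),
    centroid = .default_centroids(),
    hemispheres = hemispheres,
    parcellation = "functional-39"
  )
}

#' A synthetic 180-parcel whole-cortex area set
#'
#' Control-analysis variant emulating a whole-surface parcellation: the 39
#' visual/attention areas plus additional parcels with no planted coupling
#' to the simulated thalamus (they carry only weak global signal), used to
#' check that network recovery survives dilution of the correlation profile
#' by non-visual cortex.
#'
#' @param hemispheres subset of `c("L", "R")`.
#' @param n_parcels total parcels per hemisphere (default 180).
#' @return an `area_set` with network labels `occipito-temporal`,
#'   `fronto-parietal` and `none`.
#' @export
hcp_area_set <- function(hemispheres = c("L", "R"), n_parcels = 180) {
  base <- length(.ventral_area_names) + length(.dorsal_area_names)
  stopifnot(n_parcels > base)
  n_extra <- n_parcels - base
  extra_names <- sprintf("parcel%03d", seq_len(n_extra))
  g <- seq(0, 1, length.out = n_extra)
  extra_cent <- cbind(x = 10 + 40 * g, y = 60 - 140 * g, z = 20 * cos(2 * pi * g))
  area_set(
    names = c(.ventral_area_names, .dorsal_area_names, extra_names),
    network = c(rep("occipito-temporal", length(.ventral_area_names)),
                rep("fronto-parietal", length(.dorsal_area_names)),
                rep("none", n_extra)),
    gradient = c(seq(0, 1, length.out = length(.ventral_area_names)),
                 seq(0, 1, length.out = length(.dorsal_area_names)),
                 g),
    centroid = rbind(.default_centroids(), extra_cent),
    hemispheres = hemispheres,
    parcellation = "hcp-180"
  )
}
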