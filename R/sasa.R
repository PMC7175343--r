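#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic numerical SASA: each atom is inflated by the probe radius and
#' covered with a quasi-uniform point mesh (golden-spiral construction);
#' the accessible area is the fraction of mesh points not buried inside any
#' neighboring inflated atom. Heavy atoms only; Bondi van der Waals radii.
#'
#' @param xyz N x 3 matrix of atom coordinates (Angstrom).
#' @param elements Element symbols (length N); unknown elements get the
#'   carbon radius with a warning.
#' @param n_points Mesh points per atom (default 960).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @return Numeric vector of per-atom accessible areas (Angstrom^2).
#' @export
#' @examples
#' # lone atom: full sphere area 4*pi*(r+probe)^2
#' shrake_rupley(matrix(0, 1, 3), "C")
shrake_rupley <- function(xyz, elements, n_points = 960, probe = 1.4) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  elements <- toupper(elements)
  r <- .vdw_radius[elements]
  if (anyNA(r)) {
    warning("unknown elements treated as carbon: ",
            paste(unique(elements[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- .vdw_radius[["C"]]
  }
  r <- unname(r) + probe
  mesh <- .sphere_mesh(n_points)

  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    pts <- sweep(mesh * r[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        free <- free & dj2 > r[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    area[i] <- 4 * pi * r[i]^2 * frac
  }
  area
}

## quasi-uniform points on the unit sphere (Fibonacci / golden-angle spiral)
.sphere_mesh <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
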