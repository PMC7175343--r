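# File formats: bead-model TSV, extended XYZ trajectories, profile TSV,
# JSON run summaries.

#' Write a bead model as TSV
#'
#' Columns: index, label, chain, x, y, z, radius, charge, mass.
#'
#' @param model A [bead_model()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_bead_tsv <- function(model, path) {
  utils::write.table(as.data.frame(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a bead model from TSV
#'
#' Inverse of [write_bead_tsv()]; bonds are re-created for consecutive
#' beads if `rigid = FALSE`.
#'
#' @param path TSV file.
#' @param rigid Whether the model is rigid (default TRUE).
#' @return A [bead_model()].
#' @export
read_bead_tsv <- function(path, rigid = TRUE) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  n <- nrow(d)
  bonds <- if (rigid) NULL else cbind(seq_len(n - 1), 2:n)
  bead_model(cbind(d$x, d$y, d$z), radius = d$radius, charge = d$charge,
             mass = d$mass, label = d$label, bonds = bonds, rigid = rigid,
             chain = if ("chain" %in% names(d)) d$chain else NULL)
}

#' Write configurations as extended XYZ
#'
#' One frame per configuration: bead count, a comment line with the frame
#' index and energy, then `label x y z` rows. Readable by common
#' molecular viewers.
#'
#' @param samples A `sample_set`, or a list of N x 3 matrices.
#' @param path Output file.
#' @param labels Bead labels (taken from the system for sample sets).
#' @return The path, invisibly.
#' @export
write_xyz <- function(samples, path, labels = NULL) {
  if (inherits(samples, "sample_set")) {
    labels <- samples$sys$model$label
    energy <- samples$energy
    frames <- samples$positions
  } else {
    frames <- samples
    energy <- rep(NA_real_, length(frames))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    p <- frames[[k]]
    lb <- if (is.null(labels)) rep("X", nrow(p)) else labels
    writeLines(c(sprintf("%d", nrow(p)),
                 sprintf("frame=%d energy_kBT=%.6f", k, energy[k]),
                 sprintf("%-6s %12.5f %12.5f %12.5f", lb, p[, 1], p[, 2],
                         p[, 3])), con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' @param path File written by [write_xyz()].
#' @return List with `positions` (list of matrices), `labels`, `energy`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); energy <- numeric(0); labels <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    cm <- lines[i + 1L]
    e <- suppressWarnings(as.numeric(sub(".*energy_kBT=", "", cm)))
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    labels <- vapply(rows, `[[`, character(1), 1)
    pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- pos
    energy <- c(energy, e)
    i <- i + 2L + n
  }
  list(positions = frames, labels = labels, energy = energy)
}

#' Write a profile as TSV
#'
#' Columns: bin_left, bin_right, value, stderr.
#'
#' @param profile A [new_profile()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' JSON run summary
#'
#' Serializes everything needed to reproduce and re-analyze a run: the
#' full parameter set (with defaults resolved), the physical-constants
#' table, the seed and schedule, acceptance statistics and headline
#' observables.
#'
#' @param samples A `sample_set`.
#' @param path Output file (NULL to return the list without writing).
#' @param observables Optional named list of scalar summaries to embed.
#' @return The summary list, invisibly if written.
#' @export
write_run_summary <- function(samples, path = NULL, observables = list()) {
  sys <- samples$sys
  s <- list(
    package_version = as.character(utils::packageVersion("cgadsorb")),
    constants = physical_constants(),
    conditions = unclass(sys$conditions),
    derived = list(debye_length_A = 1 / sys$kappa, bjerrum_length_A = sys$lB,
                   gamma0 = sys$gamma0),
    layout = list(kind = sys$layout$kind, rho_e_per_A2 = sys$layout$rho,
                  spacing_A = sys$layout$spacing,
                  n_nanoparticles = length(sys$np_R),
                  np_radius_A = if (length(sys$np_R)) sys$np_R[1] else NULL,
                  np_charge_e = if (length(sys$np_Z)) sys$np_Z[1] else NULL,
                  cell_A = c(sys$Lx, sys$Ly, sys$Lz)),
    model = list(n_beads = n_beads(sys$model), rigid = sys$model$rigid,
                 net_charge_e = net_charge(sys$model)),
    energy_terms = list(use_dh = sys$use_dh, use_lj = sys$use_lj,
                        hard_core = sys$hard_core, cutoff_A = sys$cutoff,
                        bond = unclass(sys$bond), pair = unclass(sys$pair)),
    schedule = unclass(samples$schedule),
    acceptance = samples$acceptance,
    max_energy_drift_kBT = samples$max_drift,
    n_samples = length(samples$positions),
    observables = observables)
  if (is.null(path)) return(s)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(s)
}
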