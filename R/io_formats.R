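## Text formats: gmx-rama xvg, plain-text grid matrices, GROMACS
## [ dihedraltypes ] fragments, Gaussian-model and potential parameter files,
## delimited Karplus / observation / VCD tables.  All writers print enough
## digits for their paired reader to reproduce the object exactly at the
## documented precision; all readers reject malformed input rather than
## silently coercing it.

fmt17 <- function(x) sprintf("%.17g", x)

#' Read a gmx-rama style xvg file
#'
#' Lines beginning with `#` or `@` are skipped; remaining lines are parsed
#' as "phi psi label".  Angles are wrapped into (-180, 180].
#'
#' @param path File path or connection.
#' @param label Optional residue-label filter; only matching records kept.
#' @return Data frame with columns `phi`, `psi`, `label`, in file order.
#' @export
read_rama_xvg <- function(path, label = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("no data lines in xvg input")
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  nfield <- lengths(parts)
  bad <- which(nfield < 3)
  if (length(bad)) {
    stop(sprintf("malformed xvg data line %d: '%s'", idx[bad[1]], lines[idx[bad[1]]]))
  }
  phi <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  psi <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  bad <- which(!is.finite(phi) | !is.finite(psi))
  if (length(bad)) {
    stop(sprintf("malformed xvg data line %d: '%s'", idx[bad[1]], lines[idx[bad[1]]]))
  }
  lab <- vapply(parts, function(p) paste(p[-(1:2)], collapse = " "), "")
  out <- data.frame(phi = wrap_angle(phi), psi = wrap_angle(psi),
                    label = lab, stringsAsFactors = FALSE)
  if (!is.null(label)) out <- out[out$label %in% label, , drop = FALSE]
  out
}

#' Write a gmx-rama style xvg file
#'
#' @param records Data frame with columns `phi`, `psi`, `label`.
#' @param path Output path or connection.
#' @export
write_rama_xvg <- function(records, path) {
  header <- c("# backbone dihedral time series",
              "@    xaxis  label \"phi\"", "@    yaxis  label \"psi\"")
  body <- sprintf("%.6f %.6f %s", records$phi, records$psi, records$label)
  writeLines(c(header, body), path)
}

#' Write a distribution as a plain-text grid matrix
#'
#' Header lines record the bin centers; the body holds `n_phi` rows by
#' `n_psi` columns of probabilities at 17 significant digits, so the
#' write/read round trip is lossless.
#'
#' @param P A [rama_distribution()].
#' @param path Output path or connection.
#' @export
write_grid_matrix <- function(P, path) {
  stopifnot(inherits(P, "rama_distribution"))
  g <- P$grid
  header <- c(sprintf("# bin_width: %s", fmt17(g$bin_width)),
              paste("# phi_centers:", paste(fmt17(g$centers_phi), collapse = " ")),
              paste("# psi_centers:", paste(fmt17(g$centers_psi), collapse = " ")),
              sprintf("# meta: %s", P$meta))
  body <- apply(P$p, 1, function(row) paste(fmt17(row), collapse = " "))
  writeLines(c(header, body), path)
}

#' Read a plain-text grid matrix
#'
#' @param path Input path or connection.
#' @return A [rama_distribution()].
#' @export
read_grid_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    ln <- grep(paste0("^# ", name, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("grid matrix header missing '", name, "'")
    sub(paste0("^# ", name, ":\\s*"), "", ln[1])
  }
  bw <- as.numeric(get_field("bin_width"))
  phic <- as.numeric(strsplit(get_field("phi_centers"), "\\s+")[[1]])
  psic <- as.numeric(strsplit(get_field("psi_centers"), "\\s+")[[1]])
  meta <- get_field("meta")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) != length(phic)) {
    stop(sprintf("grid matrix has %d data rows, expected %d",
                 length(body), length(phic)))
  }
  p <- do.call(rbind, lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(v) != length(psic) || any(!is.finite(v))) {
      stop("malformed grid matrix row ", i)
    }
    v
  }))
  grid <- angle_grid(bw)
  if (!isTRUE(all.equal(grid$centers_phi, phic)) ||
      !isTRUE(all.equal(grid$centers_psi, psic))) {
    stop("grid matrix centers do not form a uniform grid of the stated width")
  }
  meta <- if (meta %in% c("histogram", "gaussian_model", "boltzmann")) meta else "file"
  rama_distribution(p, grid, meta = meta)
}

#' Default atom-type quartets for the backbone dihedrals
#'
#' @return Named list mapping `phi` and `psi` to four atom-type names.
#' @export
default_atom_quartets <- function() {
  list(phi = c("C", "N", "CA", "C"), psi = c("N", "CA", "C", "N"))
}

#' Write a potential as a GROMACS \[ dihedraltypes \] fragment
#'
#' Emits one function-type-9 proper-dihedral line per term: four atom types,
#' function type, phase (degrees, 2 decimals), force constant (kJ/mol,
#' 6 decimals) and multiplicity, ordered phi terms first, then psi, by
#' increasing multiplicity.  Only multiplicities 1..5 are supported.
#'
#' @param pot A [fourier_potential()].
#' @param path Output path or connection.
#' @param atom_quartets Named list as from [default_atom_quartets()].
#' @param emit_zeros Write terms with zero force constant too?
#' @export
write_gromacs_dihedraltypes <- function(pot, path,
                                        atom_quartets = default_atom_quartets(),
                                        emit_zeros = FALSE) {
  stopifnot(inherits(pot, "fourier_potential"))
  if (length(pot$k_phi) > 5 || length(pot$k_psi) > 5) {
    stop("GROMACS function type 9 supports multiplicities 1..5 only")
  }
  lines <- c(sprintf("; generated by ramaibi %s",
                     as.character(utils::packageVersion("ramaibi"))),
             "[ dihedraltypes ]",
             ";  ai    aj    ak    al  func     phase        kd  mult")
  term_lines <- function(quartet, k, gamma) {
    out <- character(0)
    for (n in seq_along(k)) {
      if (k[n] == 0 && !emit_zeros) next
      out <- c(out, sprintf("%5s %5s %5s %5s     9  %8.2f  %12.6f  %d",
                            quartet[1], quartet[2], quartet[3], quartet[4],
                            gamma[n], k[n], n))
    }
    out
  }
  lines <- c(lines,
             term_lines(atom_quartets$phi, pot$k_phi, pot$gamma_phi),
             term_lines(atom_quartets$psi, pot$k_psi, pot$gamma_psi))
  writeLines(lines, path)
}

#' Read a GROMACS \[ dihedraltypes \] fragment
#'
#' Inverse of [write_gromacs_dihedraltypes()] on its own dialect.  Function
#' types other than 9 are rejected with the offending line.
#'
#' @param path Input path or connection.
#' @return Named list (one entry per atom quartet, key
#'   `"ai-aj-ak-al"`) of lists with `k` and `gamma` vectors indexed by
#'   multiplicity.
#' @export
read_gromacs_dihedraltypes <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub(";.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln) || grepl("^\\[", ln)) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != 8) stop(sprintf("malformed dihedraltypes line %d: '%s'", i, lines[i]))
    if (f[5] != "9") {
      stop(sprintf("unsupported dihedral function type '%s' at line %d (only type 9 is supported)",
                   f[5], i))
    }
    phase <- as.numeric(f[6]); k <- as.numeric(f[7]); mult <- as.integer(f[8])
    if (!is.finite(phase) || !is.finite(k) || is.na(mult) || mult < 1 || mult > 5) {
      stop(sprintf("malformed dihedraltypes line %d: '%s'", i, lines[i]))
    }
    key <- paste(f[1:4], collapse = "-")
    if (is.null(out[[key]])) out[[key]] <- list(k = numeric(5), gamma = numeric(5))
    out[[key]]$k[mult] <- k
    out[[key]]$gamma[mult] <- phase
  }
  out
}

#' Rebuild a potential from a parsed dihedraltypes fragment
#'
#' @param parsed Output of [read_gromacs_dihedraltypes()].
#' @param atom_quartets Named list as from [default_atom_quartets()].
#' @return A [fourier_potential()] (offset 0; it is never exported).
#' @export
potential_from_dihedraltypes <- function(parsed,
                                         atom_quartets = default_atom_quartets()) {
  pick <- function(angle) {
    key <- paste(atom_quartets[[angle]], collapse = "-")
    entry <- parsed[[key]]
    if (is.null(entry)) list(k = numeric(5), gamma = numeric(5)) else entry
  }
  p <- pick("phi"); s <- pick("psi")
  fourier_potential(p$k, s$k, p$gamma, s$gamma)
}

#' Write a Gaussian model parameter file
#'
#' Whitespace-delimited table with the fixed header
#' `name weight phi psi sigma_phi sigma_psi`; values at 17 significant
#' digits for an exact round trip.
#'
#' @param model A [gaussian_rama_model()].
#' @param path Output path or connection.
#' @export
write_gaussian_model <- function(model, path) {
  stopifnot(inherits(model, "gaussian_rama_model"))
  lines <- c("# gaussian rama model",
             "name weight phi psi sigma_phi sigma_psi")
  for (cm in model$components) {
    lines <- c(lines, paste(cm$name, fmt17(cm$weight),
                            fmt17(cm$center[1]), fmt17(cm$center[2]),
                            fmt17(cm$sigma[1]), fmt17(cm$sigma[2])))
  }
  writeLines(lines, path)
}

#' Read a Gaussian model parameter file
#'
#' @param path Input path or connection.
#' @param normalization Passed to [gaussian_rama_model()].
#' @return A [gaussian_rama_model()].
#' @export
read_gaussian_model <- function(path, normalization = "exact") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("Gaussian model file has no components")
  expected <- c("name", "weight", "phi", "psi", "sigma_phi", "sigma_psi")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (!identical(hdr, expected)) {
    stop("unknown Gaussian model columns: ",
         paste(setdiff(hdr, expected), collapse = ", "))
  }
  comps <- lapply(lines[-1], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 6) stop("malformed Gaussian model line: '", ln, "'")
    v <- suppressWarnings(as.numeric(f[2:6]))
    if (any(!is.finite(v))) stop("malformed Gaussian model line: '", ln, "'")
    gaussian_component(f[1], v[1], v[2:3], v[4:5])
  })
  gaussian_rama_model(comps, normalization = normalization)
}

#' Write a Fourier potential parameter file
#'
#' Structured text: `offset`, then one `phi n k gamma` / `psi m k gamma`
#' line per term, at 17 significant digits (exact round trip).
#'
#' @param pot A [fourier_potential()].
#' @param path Output path or connection.
#' @export
write_potential_file <- function(pot, path) {
  stopifnot(inherits(pot, "fourier_potential"))
  lines <- c("# fourier dihedral potential (kJ/mol, degrees)",
             paste("offset", fmt17(pot$offset)))
  for (n in seq_along(pot$k_phi)) {
    lines <- c(lines, paste("phi", n, fmt17(pot$k_phi[n]), fmt17(pot$gamma_phi[n])))
  }
  for (m in seq_along(pot$k_psi)) {
    lines <- c(lines, paste("psi", m, fmt17(pot$k_psi[m]), fmt17(pot$gamma_psi[m])))
  }
  writeLines(lines, path)
}

#' Read a Fourier potential parameter file
#'
#' @param path Input path or connection.
#' @return A [fourier_potential()].
#' @export
read_potential_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  offset <- 0
  terms <- list(phi = list(), psi = list())
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (f[1] == "offset") {
      offset <- as.numeric(f[2])
    } else if (f[1] %in% c("phi", "psi") && length(f) == 4) {
      n <- as.integer(f[2])
      terms[[f[1]]][[n]] <- c(as.numeric(f[3]), as.numeric(f[4]))
    } else {
      stop("unknown potential file entry: '", ln, "'")
    }
  }
  unpack <- function(lst) {
    if (!length(lst)) return(list(k = numeric(1), gamma = numeric(1)))
    m <- do.call(rbind, lapply(lst, function(x) if (is.null(x)) c(0, 0) else x))
    list(k = m[, 1], gamma = m[, 2])
  }
  p <- unpack(terms$phi); s <- unpack(terms$psi)
  fourier_potential(p$k, s$k, p$gamma, s$gamma, offset)
}

#' Read a Karplus parameter table
#'
#' Whitespace/tab-delimited with header `coupling_name A B C theta0
#' depends_on s_A s_B s_C`; `NA` marks unavailable parameter uncertainties.
#'
#' @param path Input path or connection.
#' @return Data frame (one row per coupling), accepted anywhere the package
#'   takes Karplus parameters.
#' @export
read_karplus_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("coupling_name", "A", "B", "C", "theta0", "depends_on",
            "s_A", "s_B", "s_C")
  if (!all(need %in% names(df))) {
    stop("Karplus table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!all(df$depends_on %in% c("phi", "psi"))) {
    stop("Karplus 'depends_on' must be 'phi' or 'psi'")
  }
  df
}

#' Read a J-coupling observation table
#'
#' Whitespace/tab-delimited with header `coupling_name J_exp s_J`.
#'
#' @param path Input path or connection.
#' @return Data frame accepted anywhere the package takes observations.
#' @export
read_observations_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("coupling_name", "J_exp", "s_J")
  if (!all(need %in% names(df))) {
    stop("observation table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(!is.finite(df$s_J)) || any(df$s_J <= 0)) {
    stop("observation table 's_J' must be positive")
  }
  df
}

#' Write a VCD profile as two/three-column text
#'
#' @param profile A [vcd_profile_object()].
#' @param path Output path or connection.
#' @export
write_vcd_profile <- function(profile, path) {
  stopifnot(inherits(profile, "vcd_profile"))
  lines <- c("# wavenumber delta_epsilon s_k",
             paste(fmt17(profile$wavenumbers), fmt17(profile$delta_epsilon),
                   fmt17(profile$s_k)))
  writeLines(lines, path)
}

#' Read a VCD profile from two/three-column text
#'
#' @param path Input path or connection.
#' @param s_k Default standard error when the file has only two columns.
#' @return A [vcd_profile_object()].
#' @export
read_vcd_profile <- function(path, s_k = 1) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("VCD profile needs wavenumber and delta_epsilon columns")
  vcd_profile_object(df[[1]], df[[2]], if (ncol(df) >= 3) df[[3]] else s_k)
}
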