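lvc_schema_version <- 2L

#' Write / read an LVC model as JSON
#'
#' The canonical on-disk format is a versioned, human-diffable JSON document:
#' `schema_version`, `states` (array of label/fragment/character/symmetry/
#' oscillator_strength records), `modes` (frequencies, optional labels and
#' irreps), `constant_matrix` (N x N), and `couplings` (N x N x F nested
#' arrays, `couplings[i][j][alpha]`). Numbers are written at full double
#' precision so write -> read is the identity.
#'
#' Version 1 documents (flat `frequencies` plus a `lambda` coupling key) are
#' migrated transparently with a message. Unknown fields are rejected with
#' their JSON path.
#'
#' @param model An [lvc_model()].
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   an [lvc_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "lvc_model"))
  doc <- list(
    schema_version = lvc_schema_version,
    states = model$states,
    modes = list(frequencies = model$modes$frequencies,
                 labels = model$modes$labels,
                 symmetry = model$modes$symmetry),
    constant_matrix = model$constant_matrix,
    couplings = couplings_to_nested(model$couplings)
  )
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       always_decimal = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

couplings_to_nested <- function(arr) {
  n <- dim(arr)[1]
  purrr::map(seq_len(n), function(i) {
    purrr::map(seq_len(n), function(j) as.numeric(arr[i, j, ]))
  })
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- doc$schema_version %||% 1L
  if (ver == 1L) {
    message("migrating LVC model '", path, "' from schema version 1")
    doc <- migrate_model_v1(doc)
  } else if (ver != lvc_schema_version) {
    stop("unsupported LVC model schema version ", ver, " in ", path, call. = FALSE)
  }
  check_fields(doc, c("schema_version", "states", "modes", "constant_matrix",
                      "couplings"), "$")
  check_fields(doc$modes, c("frequencies", "labels", "symmetry"), "$.modes")
  states <- purrr::map(doc$states, function(s) {
    check_fields(s, c("label", "fragment", "character", "symmetry",
                      "oscillator_strength"), "$.states[]")
    s
  })
  states <- lvc_states(
    purrr::map_chr(states, "label"),
    purrr::map_chr(states, "character"),
    purrr::map_chr(states, "symmetry"),
    purrr::map_chr(states, ~ .x$fragment %||% NA_character_),
    purrr::map_dbl(states, "oscillator_strength")
  )
  modes <- normal_modes(
    as.numeric(unlist(doc$modes$frequencies)),
    labels = if (is.null(doc$modes$labels)) NULL else as.character(unlist(doc$modes$labels)),
    symmetry = if (is.null(doc$modes$symmetry)) NULL else as.character(unlist(doc$modes$symmetry))
  )
  n <- nrow(states); f <- modes$n_modes
  cm <- do.call(rbind, purrr::map(doc$constant_matrix, ~ as.numeric(unlist(.x))))
  arr <- array(0, dim = c(n, n, f))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- as.numeric(unlist(doc$couplings[[i]][[j]]))
    if (length(v) != f) {
      stop("couplings[", i, "][", j, "] has length ", length(v),
           " but the model has ", f, " modes (at $.couplings)", call. = FALSE)
    }
    arr[i, j, ] <- v
  }
  lvc_model(modes, states, cm, arr, check_symmetry = "none")
}

migrate_model_v1 <- function(doc) {
  check_fields(doc, c("schema_version", "states", "frequencies", "constant_matrix",
                      "lambda"), "$")
  list(schema_version = lvc_schema_version,
       states = doc$states,
       modes = list(frequencies = doc$frequencies, labels = NULL, symmetry = NULL),
       constant_matrix = doc$constant_matrix,
       couplings = doc$lambda)
}

check_fields <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop("unexpected field at ", where, ".", extra[1], call. = FALSE)
  }
  invisible(x)
}

#' Write / read electronic-structure records as JSON
#'
#' One file per geometry; `write_records()` lays a record set out in a
#' directory as `<geometry_tag>.json` (with `+`/`-` spelled `plus`/`minus`
#' for filesystem safety) and `read_records()` loads every `*.json` in the
#' directory.
#'
#' @param record An [es_record()].
#' @param records A list of [es_record()]s.
#' @param path,dir File path / directory.
#' @return Read functions return the record(s); write functions their path
#'   invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "es_record"))
  doc <- list(schema_version = 1L,
              geometry_tag = record$geometry_tag, q = record$q,
              adiabatic_energies = record$adiabatic_energies,
              overlap = record$overlap,
              oscillator_strengths = record$oscillator_strengths,
              strategy = record$strategy)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       always_decimal = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_fields(doc, c("schema_version", "geometry_tag", "q", "adiabatic_energies",
                      "overlap", "oscillator_strengths", "strategy"), "$")
  es_record(
    doc$geometry_tag,
    as.numeric(unlist(doc$q)),
    as.numeric(unlist(doc$adiabatic_energies)),
    do.call(rbind, purrr::map(doc$overlap, ~ as.numeric(unlist(.x)))),
    oscillator_strengths = if (is.null(doc$oscillator_strengths)) NULL
      else as.numeric(unlist(doc$oscillator_strengths)),
    strategy = doc$strategy
  )
}

#' @rdname write_record
#' @export
write_records <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in records) {
    safe <- gsub("\\+", "plus", gsub("-", "minus", rec$geometry_tag))
    write_record(rec, file.path(dir, paste0(safe, ".json")))
  }
  invisible(dir)
}

#' @rdname write_record
#' @export
read_records <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  # sidecar files written next to record sets are not records
  files <- files[!basename(files) %in% c("modes.json", "run.config.json")]
  if (length(files) == 0) stop("no .json records found in ", dir, call. = FALSE)
  recs <- purrr::map(files, read_record)
  stats::setNames(recs, purrr::map_chr(recs, "geometry_tag"))
}

#' Export an LVC model as an MCTDH-style operator file
#'
#' Writes the model in the operator-file dialect used by MCTDH-family
#' wavepacket codes: an `OP_DEFINE-SECTION`, a `PARAMETER-SECTION` with one
#' annotated parameter per coefficient (frequencies `w_m<a>`, constants
#' `E_s<i>_s<j>`, gradients `kappa_s<i>_m<a>`, linear couplings
#' `lambda_s<i>_s<j>_m<a>`, all `, ev`), and a `HAMILTONIAN-SECTION` with the
#' kinetic, harmonic, electronic and linear vibronic terms. Parameters are
#' printed at full double precision so the bundled [read_mctdh_operator()]
#' recovers every coefficient exactly.
#'
#' @param model An [lvc_model()].
#' @param path Output file.
#' @param title Title line for the operator file.
#' @return `path`, invisibly.
#' @export
write_mctdh_operator <- function(model, path, title = "lvcdyn LVC model export") {
  n <- n_states(model); f <- n_modes(model)
  if (is.null(model$modes$labels)) {
    # auto-generated names are fine for export but flag it once
    warning("modes are unlabelled; using generated names m01, m02, ...", call. = FALSE)
  }
  num <- function(x) sprintf("%.17g", x)
  sid <- function(i) sprintf("s%02d", i)
  mid <- function(a) sprintf("m%02d", a)
  lines <- c(
    "OP_DEFINE-SECTION",
    "title", title, "end-title",
    "END-OP_DEFINE-SECTION",
    "",
    "PARAMETER-SECTION"
  )
  for (a in seq_len(f)) {
    lines <- c(lines, paste0("w_", mid(a), " = ", num(model$modes$frequencies[a]), ", ev"))
  }
  for (i in seq_len(n)) for (j in i:n) {
    v <- model$constant_matrix[i, j]
    if (i == j || v != 0) {
      lines <- c(lines, paste0("E_", sid(i), "_", sid(j), " = ", num(v), ", ev"))
    }
  }
  for (i in seq_len(n)) for (a in seq_len(f)) {
    v <- model$couplings[i, i, a]
    if (v != 0) {
      lines <- c(lines, paste0("kappa_", sid(i), "_", mid(a), " = ", num(v), ", ev"))
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) for (a in seq_len(f)) {
    v <- model$couplings[i, j, a]
    if (v != 0) {
      lines <- c(lines, paste0("lambda_", sid(i), "_", sid(j), "_", mid(a),
                               " = ", num(v), ", ev"))
    }
  }
  lines <- c(lines, "END-PARAMETER-SECTION", "", "HAMILTONIAN-SECTION")
  lines <- c(lines, paste0("modes | el", paste0(" | ", vapply(seq_len(f), mid, ""),
                                                collapse = "")))
  for (a in seq_len(f)) {
    lines <- c(lines,
               paste0("1.0*w_", mid(a), " |", a + 1, " KE"),
               paste0("0.5*w_", mid(a), " |", a + 1, " q^2"))
  }
  for (i in seq_len(n)) for (j in i:n) {
    v <- model$constant_matrix[i, j]
    if (i == j || v != 0) {
      lines <- c(lines, paste0("E_", sid(i), "_", sid(j), " |1 S", i, "&", j))
    }
  }
  for (i in seq_len(n)) for (a in seq_len(f)) {
    if (model$couplings[i, i, a] != 0) {
      lines <- c(lines, paste0("kappa_", sid(i), "_", mid(a), " |1 S", i, "&", i,
                               " |", a + 1, " q"))
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) for (a in seq_len(f)) {
    if (model$couplings[i, j, a] != 0) {
      lines <- c(lines, paste0("lambda_", sid(i), "_", sid(j), "_", mid(a),
                               " |1 S", i, "&", j, " |", a + 1, " q"))
    }
  }
  lines <- c(lines, "END-HAMILTONIAN-SECTION", "", "END-OPERATOR")
  writeLines(lines, path)
  invisible(path)
}

#' Re-parse an exported MCTDH operator file
#'
#' Minimal reader for the dialect written by [write_mctdh_operator()]; used
#' to verify that the export round-trips every coefficient. Not a general
#' MCTDH operator parser.
#'
#' @param path Operator file written by [write_mctdh_operator()].
#' @return List with `frequencies`, `constant_matrix`, `couplings` (N x N x F).
#' @export
read_mctdh_operator <- function(path) {
  lines <- readLines(path)
  a <- grep("^PARAMETER-SECTION$", lines)
  b <- grep("^END-PARAMETER-SECTION$", lines)
  if (length(a) != 1 || length(b) != 1) stop("no PARAMETER-SECTION in ", path, call. = FALSE)
  params <- lines[(a + 1):(b - 1)]
  params <- params[grepl("=", params)]
  if (!all(grepl(", ev$", params))) {
    stop("parameter line without unit annotation in ", path, call. = FALSE)
  }
  key <- trimws(sub("=.*$", "", params))
  val <- as.numeric(trimws(sub(", ev$", "", sub("^.*=", "", params))))
  names(val) <- key
  widx <- grep("^w_m", key)
  f <- length(widx)
  freq <- val[widx][order(as.integer(sub("^w_m", "", key[widx])))]
  sidx <- function(tag) as.integer(sub("^s", "", tag))
  eidx <- grep("^E_", key)
  n <- max(vapply(strsplit(key[eidx], "_"), function(p) sidx(p[2]), 1L))
  cm <- matrix(0, n, n)
  for (k in eidx) {
    p <- strsplit(key[k], "_")[[1]]
    i <- sidx(p[2]); j <- sidx(p[3])
    cm[i, j] <- cm[j, i] <- val[k]
  }
  arr <- array(0, dim = c(n, n, f))
  for (k in grep("^kappa_", key)) {
    p <- strsplit(key[k], "_")[[1]]
    i <- sidx(p[2]); a2 <- as.integer(sub("^m", "", p[3]))
    arr[i, i, a2] <- val[k]
  }
  for (k in grep("^lambda_", key)) {
    p <- strsplit(key[k], "_")[[1]]
    i <- sidx(p[2]); j <- sidx(p[3]); a2 <- as.integer(sub("^m", "", p[4]))
    arr[i, j, a2] <- arr[j, i, a2] <- val[k]
  }
  list(frequencies = unname(freq), constant_matrix = cm, couplings = arr)
}

# atomic masses (amu) for the elements that occur in nucleobase models
atomic_masses <- c(H = 1.00782503, C = 12, N = 14.0030740, O = 15.9949146,
                   P = 30.97376200, S = 31.97207117)

#' Read a geometry and mass-weighted normal modes for Cartesian displacement
#'
#' Reads a standard XYZ geometry and a plain-text normal-mode file and
#' returns the [normal_modes()] basis together with a generator that converts
#' dimensionless normal-coordinate displacements to Cartesian geometries
#' (needed to drive a real electronic-structure backend along the
#' displacement protocol). The mode file format is:
#' one header line `nmodes <F> natoms <NAT>`, then per mode a line
#' `mode <k> freq_ev <omega> [sym <a'|a''>]` followed by NAT lines of
#' mass-weighted displacement components `dx dy dz` (orthonormal in
#' mass-weighted coordinates).
#'
#' The Cartesian displacement of atom i along mode alpha for a dimensionless
#' coordinate q is \eqn{\Delta x_i = L_{i\alpha} \sqrt{\hbar/(m_i
#' \omega_\alpha)}\, q_\alpha} (in Angstrom with masses in amu and omega in
#' eV).
#'
#' @param xyz_path XYZ geometry file (Angstrom).
#' @param modes_path Mode file in the format above.
#' @param orthonormal_tol Warn when the mass-weighted modes' Gram matrix
#'   deviates from the identity by more than this.
#' @return List with `modes` ([normal_modes()]), `geometry` (tibble: element,
#'   x, y, z), `displace(q)` returning the displaced NAT x 3 coordinate
#'   matrix, and `gram_deviation`.
#' @export
read_xyz_modes <- function(xyz_path, modes_path, orthonormal_tol = 1e-6) {
  xyz <- readLines(xyz_path)
  nat <- as.integer(trimws(xyz[1]))
  rows <- strsplit(trimws(xyz[3:(2 + nat)]), "\\s+")
  elements <- vapply(rows, `[[`, "", 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  unknown <- setdiff(unique(elements), names(atomic_masses))
  if (length(unknown) > 0) {
    stop("no mass tabulated for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  masses <- atomic_masses[elements]

  ml <- readLines(modes_path)
  hdr <- strsplit(trimws(ml[1]), "\\s+")[[1]]
  f <- as.integer(hdr[2]); nat_m <- as.integer(hdr[4])
  if (nat_m != nat) {
    stop("mode file describes ", nat_m, " atoms but the geometry has ", nat,
         call. = FALSE)
  }
  freq <- numeric(f); sym <- rep(NA_character_, f)
  disp <- array(0, dim = c(nat, 3, f))
  cursor <- 2
  for (k in seq_len(f)) {
    head_k <- strsplit(trimws(ml[cursor]), "\\s+")[[1]]
    freq[k] <- as.numeric(head_k[4])
    if (length(head_k) >= 6 && head_k[5] == "sym") sym[k] <- head_k[6]
    block <- ml[(cursor + 1):(cursor + nat)]
    disp[, , k] <- t(vapply(strsplit(trimws(block), "\\s+"),
                            function(r) as.numeric(r[1:3]), numeric(3)))
    cursor <- cursor + nat + 1
  }
  lmat <- matrix(disp, nat * 3, f)
  gram_dev <- max(abs(crossprod(lmat) - diag(f)))
  if (gram_dev > orthonormal_tol) {
    warning("mass-weighted modes deviate from orthonormality by ",
            format(gram_dev), call. = FALSE)
  }
  modes <- normal_modes(freq, symmetry = if (all(is.na(sym))) NULL else sym)
  # hbar*c = 1973.269804 eV Angstrom; amu c^2 = 931494095.17 eV
  conv <- 1973.269804 / sqrt(masses * 931494095.17)
  displace <- function(q) {
    q <- as.numeric(q)
    if (length(q) != f) stop("`q` must have length ", f, call. = FALSE)
    out <- coords
    for (k in seq_len(f)) {
      if (q[k] != 0) {
        out <- out + disp[, , k] * (conv / sqrt(freq[k])) * q[k]
      }
    }
    out
  }
  list(modes = modes,
       geometry = tibble::tibble(element = elements, x = coords[, 1],
                                 y = coords[, 2], z = coords[, 3]),
       displace = displace, gram_deviation = gram_dev)
}

#' Write tidy CSV mirrors of propagation and spectrum results
#'
#' @param result A [propagate()] or [absorption_spectrum()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(result, path) {
  stopifnot(inherits(result, "lvc_propagation"))
  df <- data.frame(time = result$times, result$populations, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
write_spectrum_csv <- function(result, path) {
  stopifnot(inherits(result, "lvc_spectrum"))
  utils::write.csv(as.data.frame(result$data), path, row.names = FALSE)
  invisible(path)
}
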