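# Coordinate and table I/O.
#
# Multi-model PDB is parsed with bio3d; the (trivial) XYZ trajectory format
# and the fixed-width PDB writer are implemented here. All atom-role
# resolution goes through a RoleMap so geometry code never sees raw names.

#' Atom-role map
#'
#' Maps PDB atoms to reaction-site roles. Each entry is a
#' `"RESNAME:RESNO:ATOMNAME"` triple; `*` wildcards any field. The `dialect`
#' flag accepts the older starred sugar-atom names (`O3*`) by translating
#' them to primed ones (`O3'`) before matching.
#'
#' @param entries Named character vector: names are roles, values are
#'   `"RESNAME:RESNO:ATOMNAME"` patterns.
#' @param dialect `"primed"` (default) or `"starred"`.
#' @param include_bases If `TRUE`, atoms of residues A3, U10, DT4 and A9 not
#'   otherwise mapped become optional base roles keyed `"RES<no>:<atom>"`.
#' @return An object of class `RoleMap`.
#' @export
role_map <- function(entries = default_role_entries(), dialect = "primed",
                     include_bases = FALSE) {
  dialect <- match.arg(dialect, c("primed", "starred"))
  missing <- setdiff(required_roles(), names(entries))
  if (length(missing)) {
    stop("role map lacks required role(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(entries = entries, dialect = dialect,
                 include_bases = include_bases), class = "RoleMap")
}

#' Default role-to-atom mapping
#'
#' The package's writing convention: A3 ribose atoms in residue `A 3`, dT4
#' backbone and phosphate in `DT 4`, and the alanyl moiety in `ALA 4`
#' (Ob as `OB`, Ccarb/Ocarb as `C`/`O`, Calpha/Namino/Cbeta as `CA`/`N`/`CB`).
#'
#' @return Named character vector suitable for [role_map()].
#' @export
default_role_entries <- function() {
  c(O3p = "A:3:O3'", C3p = "A:3:C3'", O2p = "A:3:O2'", C2p = "A:3:C2'",
    C4p = "DT:4:C4'", C5p = "DT:4:C5'", O5p = "DT:4:O5'", P5p = "DT:4:P",
    OP1 = "DT:4:OP1", OP2 = "DT:4:OP2",
    Ob = "ALA:4:OB", Ccarb = "ALA:4:C", Ocarb = "ALA:4:O",
    Calpha = "ALA:4:CA", Namino = "ALA:4:N", Cbeta = "ALA:4:CB")
}

#' Read a role map from a key=value text file
#'
#' Lines of the form `role = RESNAME:RESNO:ATOMNAME`; the special keys
#' `dialect` and `include_bases` set the corresponding options. `#` starts a
#' comment.
#'
#' @param path File path.
#' @return A [role_map()].
#' @export
read_role_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1L)) != 2L
  if (any(bad)) {
    stop("unparsable role-map line ", which(bad)[1L], ": '",
         lines[which(bad)[1L]], "'", call. = FALSE)
  }
  keys <- vapply(kv, `[[`, character(1L), 1L)
  vals <- vapply(kv, `[[`, character(1L), 2L)
  dialect <- if ("dialect" %in% keys) vals[keys == "dialect"] else "primed"
  inc <- if ("include_bases" %in% keys) {
    tolower(vals[keys == "include_bases"]) %in% c("true", "yes", "1")
  } else FALSE
  keep <- !(keys %in% c("dialect", "include_bases"))
  entries <- stats::setNames(vals[keep], keys[keep])
  role_map(entries, dialect = dialect, include_bases = inc)
}

.match_pattern <- function(pat, resid, resno, elety) {
  p <- strsplit(pat, ":", fixed = TRUE)[[1L]]
  if (length(p) != 3L) stop("bad role pattern '", pat, "'", call. = FALSE)
  (p[1L] == "*" | p[1L] == resid) &
    (p[2L] == "*" | suppressWarnings(as.integer(p[2L])) == resno) &
    (p[3L] == "*" | p[3L] == elety)
}

# resolve role -> atom index for a bio3d atom table
.resolve_roles <- function(atom, rmap) {
  elety <- trimws(atom$elety)
  if (rmap$dialect == "starred") elety <- gsub("*", "'", elety, fixed = TRUE)
  resid <- trimws(atom$resid)
  resno <- atom$resno
  idx <- integer(0L)
  roles <- character(0L)
  for (role in names(rmap$entries)) {
    hit <- which(.match_pattern(rmap$entries[[role]], resid, resno, elety))
    if (length(hit) == 0L && role %in% required_roles()) {
      stop("required role '", role, "' not found in file (pattern ",
           rmap$entries[[role]], ")", call. = FALSE)
    }
    if (length(hit) > 1L) {
      stop("role '", role, "' matched ", length(hit), " atoms; patterns must ",
           "be unique", call. = FALSE)
    }
    if (length(hit) == 1L) {
      idx <- c(idx, hit)
      roles <- c(roles, role)
    }
  }
  if (rmap$include_bases) {
    base_res <- list(A3 = c("A", 3L), U10 = c("U", 10L),
                     DT4 = c("DT", 4L), A9 = c("A", 9L))
    for (key in names(base_res)) {
      br <- base_res[[key]]
      hit <- setdiff(which(resid == br[1L] & resno == as.integer(br[2L])), idx)
      if (length(hit)) {
        idx <- c(idx, hit)
        roles <- c(roles, paste0(key, ":", elety[hit]))
      }
    }
  }
  stats::setNames(idx, roles)
}

#' Read a multi-frame coordinate file into an ensemble
#'
#' Supports multi-model PDB (MODEL/ENDMDL records, parsed with bio3d) and
#' plain XYZ trajectories (self-describing when written by [write_frames()],
#' whose comment line records the role order).
#'
#' @param path File path.
#' @param rmap A [role_map()] (PDB only; ignored for XYZ, which carries its
#'   role order).
#' @param frames_per_run Declared run length; defaults to all frames in one
#'   run.
#' @param chirality_label `"L"`, `"D"` or `"unknown"` for the ensemble.
#' @return An [ensemble()], one frame per model, in file order.
#' @export
read_frames <- function(path, rmap = role_map(), frames_per_run = NULL,
                        chirality_label = "unknown") {
  first <- readLines(path, n = 1L, warn = FALSE)
  is_pdb <- grepl("^(ATOM|HETATM|MODEL|REMARK|HEADER|CRYST|TITLE)", first)
  if (is_pdb) {
    frames <- .read_pdb_frames(path, rmap)
  } else {
    frames <- .read_xyz_frames(path)
  }
  n <- length(frames)
  if (is.null(frames_per_run)) frames_per_run <- n
  if (n %% frames_per_run != 0L) {
    stop(n, " frames do not partition into runs of ", frames_per_run,
         call. = FALSE)
  }
  ensemble(frames, n_runs = n %/% frames_per_run,
           frames_per_run = frames_per_run,
           system_label = basename(path), chirality_label = chirality_label)
}

.read_pdb_frames <- function(path, rmap) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- .resolve_roles(pdb$atom, rmap)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  lapply(seq_len(nrow(xyz)), function(i) {
    co <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)[sel, , drop = FALSE]
    rownames(co) <- names(sel)
    colnames(co) <- c("x", "y", "z")
    co
  })
}

.read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) {
      stop("XYZ parse error at line ", i, ": expected atom count, got '",
           lines[i], "'", call. = FALSE)
    }
    comment <- lines[i + 1L]
    roles <- NULL
    if (grepl("roles:", comment, fixed = TRUE)) {
      roles <- strsplit(trimws(sub(".*roles:", "", comment)), "\\s+")[[1L]]
    }
    if (is.null(roles) || length(roles) != nat) {
      stop("XYZ frame at line ", i, " lacks a 'roles:' comment naming all ",
           nat, " atoms", call. = FALSE)
    }
    block <- lines[i + 1L + seq_len(nat)]
    parts <- strsplit(trimws(block), "\\s+")
    badl <- which(vapply(parts, length, integer(1L)) < 4L)
    if (length(badl)) {
      stop("XYZ parse error at line ", i + 1L + badl[1L], call. = FALSE)
    }
    co <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])),
                   numeric(3L)))
    if (anyNA(co)) {
      stop("XYZ parse error: non-numeric coordinate near line ", i + 2L,
           call. = FALSE)
    }
    rownames(co) <- roles
    colnames(co) <- c("x", "y", "z")
    frames[[length(frames) + 1L]] <- co
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in ", path, call. = FALSE)
  frames
}

# role -> (resname, resno, atomname) used when writing
.role_pdb_names <- function(roles, rmap) {
  ent <- rmap$entries
  out <- matrix("", nrow = length(roles), ncol = 3L,
                dimnames = list(roles, c("resid", "resno", "elety")))
  for (i in seq_along(roles)) {
    r <- roles[i]
    if (r %in% names(ent)) {
      p <- strsplit(ent[[r]], ":", fixed = TRUE)[[1L]]
    } else if (grepl(":", r, fixed = TRUE)) {
      # optional base atom "U10:N3" -> resname U, resno 10, atom N3
      key <- strsplit(r, ":", fixed = TRUE)[[1L]]
      resname <- sub("[0-9]+$", "", key[1L])
      resno <- sub("^[A-Za-z]+", "", key[1L])
      p <- c(resname, resno, key[2L])
    } else {
      p <- c("UNK", "99", substr(r, 1L, 4L))
    }
    out[i, ] <- p
  }
  out
}

#' Write an ensemble to a coordinate file
#'
#' `"pdb"` writes fixed-width multi-model PDB (MODEL/ENDMDL, one model per
#' frame, 1-indexed like the reports); `"xyz"` writes a plain XYZ trajectory
#' whose comment line records the role order, making it self-describing for
#' [read_frames()].
#'
#' @param x An [ensemble()].
#' @param path Output path.
#' @param format `"pdb"` or `"xyz"`.
#' @param rmap A [role_map()] supplying PDB residue/atom names.
#' @return `path`, invisibly.
#' @export
write_frames <- function(x, path, format = c("pdb", "xyz"), rmap = role_map()) {
  format <- match.arg(format)
  roles <- dimnames(x$coords)[[3L]]
  n <- n_frames(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    hdr <- paste0("roles: ", paste(roles, collapse = " "))
    elem <- substr(sub(".*:", "", roles), 1L, 1L)
    for (i in seq_len(n)) {
      writeLines(c(length(roles), hdr), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", elem,
                         x$coords[i, 1L, ], x$coords[i, 2L, ],
                         x$coords[i, 3L, ]), con)
    }
  } else {
    nm <- .role_pdb_names(roles, rmap)
    for (i in seq_len(n)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4s    %8.3f%8.3f%8.3f  1.00  0.00",
        seq_along(roles), substr(nm[, "elety"], 1L, 4L), nm[, "resid"],
        nm[, "resno"], x$coords[i, 1L, ], x$coords[i, 2L, ], x$coords[i, 3L, ]),
        con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

# ---- measures tables -------------------------------------------------------

#' Write a measures table as TSV
#'
#' One row per frame, fixed column order, angles and distances rounded to 4
#' decimals (lossless for the round-trip at that precision). Frame and run
#' indices are written 1-based, mirroring PDB MODEL numbering.
#'
#' @param measures A `GeometryMeasures` data frame (non-empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measures_table <- function(measures, path) {
  if (NROW(measures) == 0L) stop("measures table is empty", call. = FALSE)
  out <- measures[, .measure_cols]
  out$frame_id <- out$frame_id + 1L
  out$run_id <- out$run_id + 1L
  num <- vapply(out, is.numeric, logical(1L)) &
    !(names(out) %in% c("frame_id", "run_id"))
  out[num] <- lapply(out[num], function(v) sprintf("%.4f", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a measures table written by [write_measures_table()]
#'
#' @param path File path.
#' @return A `GeometryMeasures` data frame (0-based indices restored).
#' @export
read_measures_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  out$frame_id <- out$frame_id - 1L
  out$run_id <- out$run_id - 1L
  class(out) <- c("GeometryMeasures", class(out))
  out
}
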