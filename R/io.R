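#' Read a multi-model structure file into an ensemble
#'
#' Wraps bio3d's PDB/mmCIF readers. Multi-MODEL PDB files are split into
#' their MODEL blocks and each block parsed separately so that atom-set
#' consistency across models can be validated (the first discrepancy is
#' named in the error). Only the first alternate location of an atom is
#' kept, with a warning. Insertion codes are not supported.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format `"pdb"` or `"cif"` (`"mmcif"` accepted as an alias);
#'   guessed from the file extension by default.
#' @return an [nmr_ensemble()].
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "cif", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  if (format == "mmcif") format <- "cif"
  if (format == "cif") {
    pdb <- bio3d::read.cif(path, multi = TRUE, verbose = FALSE)
    return(ensemble_from_bio3d(pdb))
  }
  lines <- readLines(path)
  starts <- grep("^MODEL ", lines)
  if (length(starts) == 0L) {
    mod <- model_from_bio3d_atoms(read_pdb_block(lines))
    return(as_ensemble(list(mod), "1"))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("format error: ", length(starts), " MODEL records but ",
         length(ends), " ENDMDL records")
  ids <- trimws(substring(lines[starts], 7))
  models <- vector("list", length(starts))
  for (k in seq_along(starts))
    models[[k]] <- model_from_bio3d_atoms(read_pdb_block(lines[starts[k]:ends[k]]))
  as_ensemble(models, ids)
}

## parse a vector of PDB lines through bio3d::read.pdb (via a tempfile)
read_pdb_block <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(c(lines, "END"), tf)
  pdb <- tryCatch(bio3d::read.pdb(tf, verbose = FALSE),
                  error = function(e) stop("format error: ", conditionMessage(e)))
  pdb$atom
}

model_from_bio3d_atoms <- function(at) {
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0L) stop("format error: no atom records")
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported")
  alt <- !is.na(at$alt) & nzchar(at$alt) & at$alt != "A"
  if (any(alt)) {
    warning("dropping ", sum(alt), " alternate-location atom(s); keeping the first altloc")
    at <- at[!alt, , drop = FALSE]
  }
  dup <- duplicated(paste(at$chain, at$resno, at$elety))
  if (any(dup)) at <- at[!dup, , drop = FALSE]
  ch <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
  data.frame(chain = ch, resno = as.integer(at$resno), resname = at$resid,
             atom = at$elety, x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}

ensemble_from_bio3d <- function(pdb) {
  at <- pdb$atom
  mod1 <- model_from_bio3d_atoms(at)
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1L) {
    models <- lapply(seq_len(nrow(xyz)), function(k) {
      m <- mod1
      co <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
      m$x <- co[, 1L]; m$y <- co[, 2L]; m$z <- co[, 3L]
      m
    })
    as_ensemble(models)
  } else as_ensemble(list(mod1), "1")
}

#' Write an ensemble as a multi-MODEL PDB file
#'
#' Coordinates are written at the standard PDB precision of 3 decimals, so
#' a write/read round trip reproduces them to 0.001 A. Negative residue
#' numbers are preserved.
#'
#' @param ens an [nmr_ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "nmr_ensemble"))
  if (n_models(ens) < 1L || nrow(ens$atoms) == 0L) stop("empty ensemble")
  at <- ens$atoms
  name4 <- ifelse(nchar(at$atom) < 4L, sprintf(" %-3s", at$atom), at$atom)
  elem <- sub("^[0-9]*", "", at$atom)
  elem <- toupper(substring(elem, 1L, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_models(ens))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), name4, substr(at$resname, 1L, 3L), at$chain, at$resno,
      ens$coords[, 1L, k], ens$coords[, 2L, k], ens$coords[, 3L, k],
      1, 0, elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

canonical_atom_types <- c("HN", "HA", "N", "CA", "CB", "C")

## map common shift-table atom spellings onto the canonical six backbone types
normalize_atom_type <- function(x) {
  up <- toupper(trimws(x))
  map <- c(CA = "CA", CB = "CB", C = "C", "C'" = "C", CO = "C",
           H = "HN", HN = "HN", HA = "HA", N = "N", NH = "N")
  unname(map[up])
}

#' Read a chemical-shift table
#'
#' Two dialects are supported: a TSV with header
#' `chain residue resname atom shift uncertainty`, and a minimal NMR-STAR
#' reader that extracts the `_Atom_chem_shift` loop of a BMRB-style file
#' (nothing else of the STAR grammar is interpreted). Atom names are
#' normalized to the canonical backbone six (HN, HA, N, CA, CB, C);
#' rows with unknown atom types are skipped with a warning.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"nmrstar"`.
#' @return a `shift_table` data.frame with columns `chain`, `resno`,
#'   `resname`, `atom`, `shift`, `sd`.
#' @export
read_shift_table <- function(path, dialect = c("tsv", "nmrstar")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chain", "residue", "resname", "atom", "shift")
    if (!all(need %in% names(d)))
      stop("shift TSV must have columns: ", paste(need, collapse = ", "))
    tab <- data.frame(chain = as.character(d$chain),
                      resno = as.integer(d$residue),
                      resname = toupper(d$resname),
                      atom = d$atom,
                      shift = as.numeric(d$shift),
                      sd = if ("uncertainty" %in% names(d))
                        as.numeric(d$uncertainty) else NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    tab <- read_star_shift_loop(path)
  }
  shift_table(tab)
}

#' Construct/validate a shift table
#' @param tab data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `shift` and optionally `sd`.
#' @export
shift_table <- function(tab) {
  if (!"sd" %in% names(tab)) tab$sd <- NA_real_
  canon <- normalize_atom_type(tab$atom)
  unknown <- is.na(canon)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " row(s) with unknown atom type(s): ",
            paste(unique(tab$atom[unknown]), collapse = ", "))
    tab <- tab[!unknown, , drop = FALSE]
    canon <- canon[!unknown]
  }
  tab$atom <- canon
  if (any(!is.finite(tab$shift))) stop("non-finite chemical shifts")
  if (any(!is.na(tab$sd) & tab$sd <= 0)) stop("shift uncertainties must be > 0")
  key <- paste(tab$chain, tab$resno, tab$atom)
  if (anyDuplicated(key))
    stop("duplicate shift row for (", key[duplicated(key)][1L], ")")
  rownames(tab) <- NULL
  class(tab) <- c("shift_table", "data.frame")
  tab
}

## minimal NMR-STAR: pull tag names and values of the Atom_chem_shift loop
read_star_shift_loop <- function(path) {
  lines <- readLines(path)
  i <- grep("^\\s*loop_\\s*$", lines)
  for (start in i) {
    j <- start + 1L
    tags <- character()
    while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
      tags <- c(tags, trimws(lines[j])); j <- j + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    vals <- list()
    while (j <= length(lines) && !grepl("^\\s*(stop_|loop_)", lines[j])) {
      ln <- trimws(lines[j]); j <- j + 1L
      if (!nzchar(ln) || startsWith(ln, "#")) next
      vals[[length(vals) + 1L]] <- scan(text = ln, what = "", quiet = TRUE)
    }
    field <- function(tag) {
      k <- match(paste0("_Atom_chem_shift.", tag), tags)
      if (is.na(k)) rep(NA_character_, length(vals))
      else vapply(vals, function(v) if (length(v) >= k) v[k] else NA_character_, "")
    }
    chain <- field("Entity_assembly_ID")
    chain[is.na(chain) | chain == "."] <- "A"
    sd <- suppressWarnings(as.numeric(field("Val_err")))
    return(data.frame(chain = chain,
                      resno = as.integer(field("Seq_ID")),
                      resname = toupper(field("Comp_ID")),
                      atom = field("Atom_ID"),
                      shift = as.numeric(field("Val")),
                      sd = sd, stringsAsFactors = FALSE))
  }
  stop("no _Atom_chem_shift loop found in ", path)
}

#' Read a per-residue intensity table (exchange / NOE experiments)
#'
#' TSV with header `chain residue condition delay intensity` and an
#' optional `water_intensity` column; `condition` is `saturated` or
#' `unsaturated` and `delay` is the relaxation delay in seconds.
#'
#' @param path input file.
#' @return data.frame of class `intensity_table`.
#' @export
read_intensity_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain", "residue", "condition", "delay", "intensity")
  if (!all(need %in% names(d)))
    stop("intensity TSV must have columns: ", paste(need, collapse = ", "))
  tab <- data.frame(chain = as.character(d$chain),
                    resno = as.integer(d$residue),
                    condition = d$condition,
                    delay = as.numeric(d$delay),
                    intensity = as.numeric(d$intensity),
                    water_intensity = if ("water_intensity" %in% names(d))
                      as.numeric(d$water_intensity) else NA_real_,
                    stringsAsFactors = FALSE)
  intensity_table(tab)
}

#' @rdname read_intensity_table
#' @param tab a data.frame with the intensity-table columns.
#' @export
intensity_table <- function(tab) {
  if (!"water_intensity" %in% names(tab)) tab$water_intensity <- NA_real_
  if (!all(tab$condition %in% c("saturated", "unsaturated")))
    stop("condition must be 'saturated' or 'unsaturated'")
  if (any(tab$delay < 0)) stop("negative relaxation delay")
  key <- paste(tab$chain, tab$resno, tab$condition, tab$delay)
  if (anyDuplicated(key))
    stop("duplicate intensity row for (", key[duplicated(key)][1L], ")")
  tab <- tab[order(tab$chain, tab$resno, tab$condition, tab$delay), ]
  rownames(tab) <- NULL
  class(tab) <- c("intensity_table", "data.frame")
  tab
}

#' Write a data.frame as a TSV file
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
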