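# Descriptor-table CSV input/output and XYZ constitutional descriptors.

#' Read a molecular descriptor table from CSV
#'
#' Expects a header row. Mandatory columns: `id`, `class`, `dft_nci`. The
#' reference column (default name `ref_nci`) is required unless
#' `ref_required = FALSE`. All remaining numeric columns are treated as
#' descriptors, in file order, with `dft_nci` among them. Class tokens are
#' matched case-insensitively against `h_bonded`, `dispersion`, `mixed`,
#' `halogen`, `unknown`.
#'
#' @param path CSV file path.
#' @param id_col,class_col,ref_col Column names for the identifier, the
#'   interaction class and the reference energy.
#' @param ref_required If `TRUE` (default) every row must have a finite
#'   reference value; blank cells raise an integrity error.
#' @param tag_col Optional column holding the database tag
#'   (`S22`/`S66`/`X40`/`synthetic`/`other`).
#' @return An [nci_dataset].
#' @export
read_descriptor_table <- function(path, id_col = "id", class_col = "class",
                                  ref_col = "ref_nci", ref_required = TRUE,
                                  tag_col = "database_tag") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "grnncorr_io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  for (col in c(id_col, class_col, "dft_nci")) {
    if (!col %in% names(raw)) {
      abort(sprintf("mandatory column '%s' missing from %s", col, path),
            "grnncorr_schema_error")
    }
  }
  if (ref_required && !ref_col %in% names(raw)) {
    abort(sprintf("reference column '%s' missing from %s", ref_col, path),
          "grnncorr_schema_error")
  }

  special <- c(id_col, class_col, ref_col, tag_col)
  desc_cols <- setdiff(names(raw), special)
  parse_num <- function(col, required = TRUE) {
    txt <- raw[[col]]
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) & !(txt == "" | toupper(txt) == "NA"))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' in column '%s', row %d",
                    txt[bad[1]], col, bad[1]),
            "grnncorr_parse_error")
    }
    blank <- which(txt == "" | toupper(txt) == "NA")
    if (required && length(blank)) {
      abort(sprintf("missing value in column '%s', row %d", col, blank[1]),
            "grnncorr_integrity_error")
    }
    v
  }

  df <- data.frame(id = raw[[id_col]], class = raw[[class_col]],
                   stringsAsFactors = FALSE)
  if (tag_col %in% names(raw)) df$database_tag <- raw[[tag_col]]
  for (col in desc_cols) df[[col]] <- parse_num(col, required = TRUE)
  if (ref_col %in% names(raw)) {
    df$ref_nci <- parse_num(ref_col, required = ref_required)
  }
  nci_dataset(df, desc_cols, provenance = sprintf("read from %s", path))
}

#' Write a dataset as a descriptor CSV
#'
#' Emits the dialect read back by [read_descriptor_table()]: columns `id`,
#' `class`, `database_tag`, the descriptors in order, then `ref_nci`.
#'
#' @param data An [nci_dataset].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(data, path) {
  df <- data$records
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Main-group valence electron counts, periods 1-5 (H through Xe). The valence
# is the group valence-electron count; transition metals are out of scope for
# NCI benchmark complexes.
VALENCE_ELECTRONS <- c(
  H = 1, He = 2,
  Li = 1, Be = 2, B = 3, C = 4, N = 5, O = 6, F = 7, Ne = 8,
  Na = 1, Mg = 2, Al = 3, Si = 4, P = 5, S = 6, Cl = 7, Ar = 8,
  K = 1, Ca = 2, Ga = 3, Ge = 4, As = 5, Se = 6, Br = 7, Kr = 8,
  Rb = 1, Sr = 2, In = 3, Sn = 4, Sb = 5, Te = 6, I = 7, Xe = 8
)

#' Constitutional descriptors from an XYZ file
#'
#' Parses a standard XYZ file (atom-count line, comment line, then one
#' `element x y z` row per atom) and returns the two constitutional
#' descriptors used alongside the quantum descriptors: the atom count and the
#' total number of valence electrons (main-group valence, H = 1, C = 4,
#' N = 5, O = 6, halogens = 7, ...).
#'
#' @param path XYZ file path.
#' @return List with `n_atoms` and `n_valence_electrons` (integers).
#' @examples
#' xyz <- tempfile(fileext = ".xyz")
#' writeLines(c("3", "water", "O 0 0 0.12", "H 0 0.76 -0.47",
#'              "H 0 -0.76 -0.47"), xyz)
#' constitutional_descriptors(xyz)  # 3 atoms, 8 valence electrons
#' @export
constitutional_descriptors <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "grnncorr_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (length(lines) < 3) {
    abort("not a valid XYZ file: fewer than 3 lines", "grnncorr_format_error")
  }
  n_decl <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n_decl)) {
    abort("XYZ count line is not an integer", "grnncorr_format_error")
  }
  atom_lines <- lines[-(1:2)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  if (length(atom_lines) != n_decl) {
    abort(sprintf("XYZ count line declares %d atoms but %d atom rows found",
                  n_decl, length(atom_lines)),
          "grnncorr_format_error")
  }
  elements <- vapply(strsplit(trimws(atom_lines), "\\s+"), `[[`, "", 1L)
  unknown <- setdiff(unique(elements), names(VALENCE_ELECTRONS))
  if (length(unknown)) {
    abort(sprintf("unknown element symbol(s): %s",
                  paste(unknown, collapse = ", ")),
          "grnncorr_lookup_error")
  }
  list(
    n_atoms = n_decl,
    n_valence_electrons = as.integer(sum(VALENCE_ELECTRONS[elements]))
  )
}
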