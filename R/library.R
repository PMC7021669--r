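# The predicted-spectra library: a compound table plus one predicted
# spectrum per (compound, collision energy).

PROTON_MASS <- 1.007276 # Da

#' Build a spectral library
#'
#' @param compounds Tibble with columns `compound_id`, `formula`,
#'   `monoisotopic_mass`, and optionally `name`. Formulas are stored in
#'   canonical Hill-order form.
#' @param entries Tibble with columns `compound_id`, `collision_energy`,
#'   and a `peaks` list-column of data frames (`mz`, `intensity`).
#' @return An object of class `spectral_library` (a list with `compounds`
#'   and `entries` tibbles).
#' @export
spectral_library <- function(compounds, entries) {
  compounds <- tibble::as_tibble(compounds)
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("compound_id", "formula", "monoisotopic_mass") %in%
                  names(compounds)),
            all(c("compound_id", "collision_energy", "peaks") %in%
                  names(entries)))
  if (!"name" %in% names(compounds)) compounds$name <- NA_character_
  if (anyDuplicated(compounds$compound_id)) {
    stop("duplicate compound_id in compound table")
  }
  if (any(compounds$monoisotopic_mass <= 0)) {
    stop("monoisotopic_mass must be positive")
  }
  compounds$formula <- canonical_formula(compounds$formula)
  unknown <- setdiff(entries$compound_id, compounds$compound_id)
  if (length(unknown)) {
    stop("library entries reference unknown compound_id: ",
         paste(unique(unknown), collapse = ", "))
  }
  key <- paste(entries$compound_id, entries$collision_energy)
  if (anyDuplicated(key)) {
    stop("duplicate (compound_id, collision_energy) entry: ",
         key[duplicated(key)][1])
  }
  entries$peaks <- lapply(entries$peaks, normalize_peaks)
  if (any(vapply(entries$peaks, nrow, integer(1)) == 0L)) {
    stop("library spectra must contain at least one peak")
  }
  structure(
    list(compounds = compounds,
         entries = entries[order(entries$compound_id,
                                 entries$collision_energy), ]),
    class = "spectral_library"
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("<spectral_library> ", nrow(x$compounds), " compounds, ",
      nrow(x$entries), " predicted spectra (CE ",
      paste(sort(unique(x$entries$collision_energy)), collapse = "/"),
      " V)\n", sep = "")
  invisible(x)
}

#' Neutral mass from an observed precursor m/z
#'
#' Only protonation/deprotonation adducts are considered: positive mode
#' \[M+H\]+ subtracts a proton, negative mode \[M-H\]- adds one.
#'
#' @param precursor_mz Observed precursor m/z (Da). Vectorized.
#' @param polarity `"positive"` or `"negative"`, recycled.
#' @param proton_mass Proton mass constant in Da (default 1.007276).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' neutral_mass_from_precursor(301.141076, "positive")
#' @export
neutral_mass_from_precursor <- function(precursor_mz, polarity,
                                        proton_mass = PROTON_MASS) {
  polarity <- rep_len(match.arg(polarity, c("positive", "negative"),
                                several.ok = TRUE), length(precursor_mz))
  out <- ifelse(polarity == "positive",
                precursor_mz - proton_mass,
                precursor_mz + proton_mass)
  if (any(out <= 0)) stop("non-positive neutral mass from precursor m/z")
  out
}

#' Precursor m/z of a neutral mass
#'
#' Inverse of [neutral_mass_from_precursor()] for the same adducts.
#'
#' @inheritParams neutral_mass_from_precursor
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @return Adduct m/z in Da.
#' @export
precursor_from_neutral <- function(neutral_mass, polarity,
                                   proton_mass = PROTON_MASS) {
  polarity <- rep_len(match.arg(polarity, c("positive", "negative"),
                                several.ok = TRUE), length(neutral_mass))
  ifelse(polarity == "positive",
         neutral_mass + proton_mass,
         neutral_mass - proton_mass)
}

#' Retrieve candidate compounds by neutral mass
#'
#' Returns every compound whose monoisotopic mass lies within `ppm_tol`
#' parts per million of the query mass, ordered by absolute mass error
#' (ties by `compound_id`). The ppm denominator is the query mass by
#' default, i.e. the window is centred on the observed value.
#'
#' @param library A `spectral_library`, or a compound tibble.
#' @param neutral_mass Query neutral mass in Da.
#' @param ppm_tol Relative tolerance in ppm (default 10).
#' @param ppm_reference Denominator of the ppm error: the `"query"` mass
#'   (default) or each `"candidate"` mass.
#' @return Tibble of matching compound records with an added
#'   `mass_error_ppm` column.
#' @export
candidates_by_mass <- function(library, neutral_mass, ppm_tol = 10,
                               ppm_reference = c("query", "candidate")) {
  stopifnot(ppm_tol > 0, neutral_mass > 0)
  ppm_reference <- match.arg(ppm_reference)
  compounds <- if (inherits(library, "spectral_library")) {
    library$compounds
  } else {
    tibble::as_tibble(library)
  }
  denom <- if (ppm_reference == "query") neutral_mass else
    compounds$monoisotopic_mass
  err <- (compounds$monoisotopic_mass - neutral_mass) / denom * 1e6
  hit <- abs(err) <= ppm_tol
  out <- compounds[hit, , drop = FALSE]
  out$mass_error_ppm <- err[hit]
  out[order(abs(out$mass_error_ppm), out$compound_id), ]
}

#' Restrict candidates to a molecular formula
#'
#' Keeps candidates whose formula equals `target` (element counts compared
#' via canonical rendering); input order is preserved. Never adds
#' candidates.
#'
#' @param candidates Tibble of compound records with a `formula` column.
#' @param target Target formula string.
#' @return Subset of `candidates`.
#' @export
filter_by_formula <- function(candidates, target) {
  target <- canonical_formula(target)
  candidates[canonical_formula(candidates$formula) == target, , drop = FALSE]
}

#' Read a compound database table
#'
#' TSV or CSV with columns `compound_id`, `formula`, `monoisotopic_mass`
#' and optional `name`.
#'
#' @param path Path to the table; delimiter inferred from the extension.
#' @return Compound tibble.
#' @export
read_compound_db <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  db <- reader(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("compound_id", "formula", "monoisotopic_mass") %in%
                  names(db)))
  db$compound_id <- as.character(db$compound_id)
  db
}

#' Load a predicted-spectra library from disk
#'
#' @param compounds_path Compound table (TSV/CSV, see [read_compound_db()]).
#' @param spectra_path Predicted spectra in the named dialect.
#' @param format `"msp"` (NIST-style blocks, collision energy carried in a
#'   `Comment: collision_energy=<V>` field), `"json"` (array of records
#'   with `compound_id`, `collision_energy`, `mz`, `intensity`), or
#'   `"tsv"` (long table with those four columns).
#' @return A `spectral_library`.
#' @export
load_library <- function(compounds_path, spectra_path,
                         format = c("msp", "json", "tsv")) {
  format <- match.arg(format)
  compounds <- read_compound_db(compounds_path)
  entries <- switch(format,
    msp = read_msp(spectra_path),
    json = read_library_json(spectra_path),
    tsv = read_library_tsv(spectra_path)
  )
  spectral_library(compounds, entries)
}

#' Read predicted spectra from a NIST-style MSP file
#'
#' Blocks of `Name:` / optional `PrecursorMZ:` / `Comment:` /
#' `Num Peaks:` followed by whitespace-separated peak pairs; the compound
#' id is the `Name` and the collision energy is taken from a
#' `collision_energy=<V>` token in the `Comment` field.
#'
#' @param path Path to the MSP file.
#' @return Entries tibble (`compound_id`, `collision_energy`, `peaks`,
#'   `precursor_mz`).
#' @export
read_msp <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  starts <- which(grepl("^Name:", lines))
  bounds <- c(starts, length(lines) + 1L)
  rows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    body <- trimws(lines[seq(bounds[i], bounds[i + 1L] - 1L)])
    body <- body[nzchar(body)]
    fields <- grep("^[A-Za-z][A-Za-z ]*:", body, value = TRUE)
    get_field <- function(key) {
      hit <- grep(paste0("^", key, ":"), fields, value = TRUE)
      if (!length(hit)) return(NULL)
      trimws(sub(paste0("^", key, ":"), "", hit[1]))
    }
    name <- get_field("Name")
    comment <- get_field("Comment") %||% ""
    ce_match <- stringr::str_match(comment, "collision_energy=([0-9.]+)")[, 2]
    if (is.na(ce_match)) {
      stop("MSP block for '", name, "': no collision_energy in Comment")
    }
    peak_lines <- body[!grepl("^[A-Za-z][A-Za-z ]*:", body)]
    mat <- stringr::str_split_fixed(peak_lines, "[\\s;]+", 2)
    mz <- as.numeric(mat[, 1])
    intensity <- as.numeric(mat[, 2])
    if (anyNA(mz) || anyNA(intensity)) {
      stop("MSP block for '", name, "': non-numeric peak line")
    }
    n_declared <- get_field("Num Peaks")
    if (!is.null(n_declared) && as.integer(n_declared) != length(mz)) {
      stop("MSP block for '", name, "': Num Peaks mismatch")
    }
    pmz <- get_field("PrecursorMZ")
    rows[[i]] <- tibble::tibble(
      compound_id = name,
      collision_energy = as.numeric(ce_match),
      peaks = list(tibble::tibble(mz = mz, intensity = intensity)),
      precursor_mz = if (is.null(pmz)) NA_real_ else as.numeric(pmz)
    )
  }
  dplyr::bind_rows(rows)
}

#' Write predicted spectra as MSP
#'
#' @param entries Entries tibble as stored in a `spectral_library`
#'   (columns `compound_id`, `collision_energy`, `peaks`, optionally
#'   `precursor_mz`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(entries, path) {
  has_pmz <- "precursor_mz" %in% names(entries)
  blocks <- purrr::pmap(
    list(entries$compound_id, entries$collision_energy, entries$peaks,
         if (has_pmz) entries$precursor_mz else rep(NA_real_, nrow(entries))),
    function(id, ce, peaks, pmz) {
      c(paste0("Name: ", id),
        if (!is.na(pmz)) sprintf("PrecursorMZ: %.6f", pmz),
        sprintf("Comment: collision_energy=%g", ce),
        paste0("Num Peaks: ", nrow(peaks)),
        sprintf("%.6f %.6g", peaks$mz, peaks$intensity),
        "")
    })
  writeLines(unlist(blocks), path)
  invisible(path)
}

read_library_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  dplyr::bind_rows(lapply(recs, function(r) {
    tibble::tibble(
      compound_id = r$compound_id,
      collision_energy = as.numeric(r$collision_energy),
      peaks = list(tibble::tibble(mz = as.numeric(unlist(r$mz)),
                                  intensity = as.numeric(unlist(r$intensity)))),
      precursor_mz = as.numeric(r$precursor_mz %||% NA_real_)
    )
  }))
}

read_library_tsv <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("compound_id", "collision_energy", "mz", "intensity") %in%
                  names(long)))
  tidyr::nest(long, peaks = c("mz", "intensity"))
}

#' Look up one predicted spectrum
#'
#' @param library A `spectral_library`.
#' @param compound_id Compound id.
#' @param collision_energy Collision energy in volts.
#' @return The peaks tibble, or `NULL` when the entry is absent.
#' @export
library_spectrum <- function(library, compound_id, collision_energy) {
  hit <- library$entries$compound_id == compound_id &
    library$entries$collision_energy == collision_energy
  if (!any(hit)) return(NULL)
  library$entries$peaks[[which(hit)[1]]]
}
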