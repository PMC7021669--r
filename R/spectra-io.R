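# MS2 spectra live in a plain tibble, one row per spectrum, with the peak
# list as a list-column of two-column tibbles (mz, intensity). That keeps
# every downstream step a normal dplyr pipeline.

#' Construct a spectra tibble
#'
#' Low-level constructor used by the readers and the synthetic generator.
#' Peak lists are normalized: zero-intensity peaks dropped, peaks sorted
#' ascending by m/z, duplicate m/z merged by summing intensity.
#'
#' @param spectrum_id Character vector of unique spectrum ids.
#' @param precursor_mz Precursor m/z values (Da), all `> 0`.
#' @param polarity `"positive"` or `"negative"`, recycled if length 1.
#' @param collision_energy Collision energy in volts, recycled if length 1.
#' @param peaks List of data frames with columns `mz` and `intensity`.
#' @param source_file,mixture_id Optional provenance strings.
#' @param metadata Optional list of per-spectrum key/value lists.
#' @return A tibble with one row per spectrum and a `peaks` list-column.
#' @export
spectra_tibble <- function(spectrum_id, precursor_mz, polarity,
                           collision_energy, peaks,
                           source_file = NA_character_,
                           mixture_id = NA_character_,
                           metadata = NULL) {
  n <- length(spectrum_id)
  stopifnot(length(peaks) == n, length(precursor_mz) == n)
  if (anyDuplicated(spectrum_id)) stop("spectrum_id values must be unique")
  if (any(precursor_mz <= 0)) stop("precursor_mz must be positive")
  polarity <- rep_len(match.arg(polarity, c("positive", "negative"),
                                several.ok = TRUE), n)
  tibble::tibble(
    spectrum_id = as.character(spectrum_id),
    precursor_mz = as.numeric(precursor_mz),
    polarity = polarity,
    collision_energy = rep_len(as.numeric(collision_energy), n),
    peaks = lapply(peaks, normalize_peaks),
    source_file = rep_len(as.character(source_file), n),
    mixture_id = rep_len(as.character(mixture_id), n),
    metadata = if (is.null(metadata)) rep(list(list()), n) else metadata
  )
}

#' Normalize a peak list
#'
#' Drops non-positive intensities, sorts ascending by m/z, and merges
#' duplicate m/z values by summing their intensities, so peak lists are
#' strictly ascending.
#'
#' @param peaks Data frame with columns `mz` and `intensity`.
#' @return A tibble with strictly ascending `mz`.
#' @export
normalize_peaks <- function(peaks) {
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  keep <- peaks$intensity > 0
  mz <- peaks$mz[keep]
  intensity <- peaks$intensity[keep]
  if (any(mz <= 0)) stop("peak m/z must be positive")
  if (length(mz) && anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  } else {
    ord <- order(mz)
    mz <- mz[ord]
    intensity <- intensity[ord]
  }
  tibble::tibble(mz = mz, intensity = intensity)
}

MGF_KNOWN_KEYS <- c("TITLE", "PEPMASS", "CHARGE", "RTINSECONDS",
                    "COLLISION_ENERGY", "COLLISIONENERGY")

#' Read MS2 spectra from a Mascot Generic Format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. The first numeric token of
#' `PEPMASS` becomes the precursor m/z; polarity comes from the sign of
#' `CHARGE` (`"1+"` positive, `"1-"` negative) unless overridden; collision
#' energy comes from a `COLLISION_ENERGY` key unless supplied. Unknown keys
#' are preserved per spectrum in the `metadata` list-column. Zero-intensity
#' peaks are dropped; a spectrum left with no peaks is skipped with a
#' warning.
#'
#' @param path Path to an MGF file.
#' @param polarity Optional file-wide polarity override
#'   (`"positive"`/`"negative"`).
#' @param collision_energy Optional file-wide collision energy (volts) used
#'   when blocks carry none.
#' @param mixture_id Optional mixture label attached to every spectrum.
#' @return A spectra tibble (see [spectra_tibble()]).
#' @export
read_mgf <- function(path, polarity = NULL, collision_energy = NULL,
                     mixture_id = NA_character_) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  begins <- which(trimws(lines) == "BEGIN IONS")
  ends <- which(trimws(lines) == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("unbalanced BEGIN IONS/END IONS in ", path)
  }
  rows <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    body <- lines[seq(begins[b] + 1L, ends[b] - 1L)]
    body <- trimws(body)
    body <- body[nzchar(body) & !startsWith(body, "#")]
    is_key <- grepl("=", body, fixed = TRUE)
    keys <- body[is_key]
    kv <- stringr::str_split_fixed(keys, "=", 2)
    key_names <- toupper(trimws(kv[, 1]))
    key_vals <- trimws(kv[, 2])
    params <- stats::setNames(as.list(key_vals), key_names)

    if (is.null(params$PEPMASS)) {
      stop("MGF block ", b, " in ", basename(path), " has no PEPMASS")
    }
    precursor_mz <- suppressWarnings(
      as.numeric(strsplit(params$PEPMASS, "\\s+")[[1]][1])
    )
    if (is.na(precursor_mz)) {
      stop("MGF block ", b, " in ", basename(path), ": non-numeric PEPMASS")
    }

    peak_lines <- body[!is_key]
    mat <- stringr::str_split_fixed(peak_lines, "\\s+", 3)
    mz <- suppressWarnings(as.numeric(mat[, 1]))
    intensity <- suppressWarnings(as.numeric(mat[, 2]))
    if (length(peak_lines) && (anyNA(mz) || anyNA(intensity))) {
      stop("MGF block ", b, " in ", basename(path), ": non-numeric peak line")
    }

    pol <- polarity %||% charge_polarity(params$CHARGE)
    if (is.null(pol)) {
      stop("MGF block ", b, " in ", basename(path),
           ": no CHARGE sign and no polarity override")
    }
    ce <- if (!is.null(params$COLLISION_ENERGY)) {
      as.numeric(params$COLLISION_ENERGY)
    } else if (!is.null(params$COLLISIONENERGY)) {
      as.numeric(params$COLLISIONENERGY)
    } else {
      collision_energy %||% NA_real_
    }

    pk <- normalize_peaks(tibble::tibble(mz = mz, intensity = intensity))
    if (nrow(pk) == 0L) {
      warning("MGF block ", b, " in ", basename(path),
              " has no peaks after cleaning; skipped", call. = FALSE)
      next
    }
    extra <- params[setdiff(names(params), MGF_KNOWN_KEYS)]
    rows[[b]] <- tibble::tibble(
      spectrum_id = params$TITLE %||% paste0(basename(path), "#", b),
      precursor_mz = precursor_mz,
      polarity = pol,
      collision_energy = ce,
      peaks = list(pk),
      source_file = basename(path),
      mixture_id = as.character(mixture_id),
      metadata = list(extra)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- spectra_tibble(character(0), numeric(0), "positive", numeric(0),
                          list())
  }
  if (anyDuplicated(out$spectrum_id)) {
    out$spectrum_id <- make.unique(out$spectrum_id, sep = "_")
  }
  out
}

# CHARGE string -> polarity; NULL when absent/signless. Accepts "1+", "2+",
# "1-" and the unicode minus some exporters emit.
charge_polarity <- function(charge) {
  if (is.null(charge)) return(NULL)
  charge <- gsub("−", "-", charge)
  if (grepl("\\+", charge)) return("positive")
  if (grepl("-", charge)) return("negative")
  NULL
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()] for the recognized keys: reading the written file
#' back recovers precursor m/z and sorted peak lists up to float formatting.
#'
#' @param spectra A spectra tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::pmap(spectra, function(spectrum_id, precursor_mz, polarity,
                                          collision_energy, peaks, ...) {
    c("BEGIN IONS",
      paste0("TITLE=", spectrum_id),
      sprintf("PEPMASS=%.6f", precursor_mz),
      paste0("CHARGE=1", if (polarity == "positive") "+" else "-"),
      if (!is.na(collision_energy))
        sprintf("COLLISION_ENERGY=%g", collision_energy),
      sprintf("%.6f %.6g", peaks$mz, peaks$intensity),
      "END IONS",
      "")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' De-duplicate replicate spectra of one precursor
#'
#' A chemical feature often yields several MS2 acquisitions of the same
#' precursor; only the most intense is kept for matching. Spectra are
#' grouped by precursor m/z with single linkage at `group_tolerance`, and
#' within each group the spectrum with the highest summed peak intensity is
#' retained (ties broken by lexicographically smallest `spectrum_id`).
#' Callers should partition by polarity and collision energy first.
#'
#' @param spectra A spectra tibble sharing polarity and collision energy.
#' @param group_tolerance Single-linkage grouping tolerance in Da
#'   (default 0.005).
#' @return Spectra tibble with one row per precursor group, ordered by
#'   ascending precursor m/z.
#' @export
deduplicate_spectra <- function(spectra, group_tolerance = 0.005) {
  if (nrow(spectra) == 0L) return(spectra)
  spectra |>
    dplyr::mutate(
      .group = single_linkage_groups(.data$precursor_mz, group_tolerance),
      .tic = vapply(.data$peaks, function(p) sum(p$intensity), numeric(1))
    ) |>
    dplyr::group_by(.data$.group) |>
    dplyr::arrange(dplyr::desc(.data$.tic), .data$spectrum_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$precursor_mz) |>
    dplyr::select(-".group", -".tic")
}

#' Write tabular results as CSV
#'
#' RFC-4180 CSV with a header row; numeric columns keep full double
#' precision so values round-trip well within 1e-6.
#'
#' @param rows A data frame of result records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(rows, path) {
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
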