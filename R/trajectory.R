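#' Assemble a photon dataset
#'
#' Bundles a tidy table of photons with optional correction factors and the
#' experiment kind. Photons are the atomic unit of the analysis: each row is
#' one detected photon with its arrival time (seconds) and detection channel
#' (`"D"`, `"A1"` or `"A2"`), grouped into trajectories labelled by the
#' active-dye segment class.
#'
#' Folding datasets may contain segment classes `3c`, `DA1`, `DA2` and
#' `Donly`; binding datasets `3c/DA1`, `DA2` and `Donly`. Times must be
#' strictly increasing within a trajectory.
#'
#' @param photons A data frame with columns `trajectory_id`, `class`, `time`
#'   (seconds) and `channel`.
#' @param corrections Optional [correction_factors()] list.
#' @param kind `"folding"` or `"binding"`.
#' @return A `fret_data` object (list with elements `photons`, `corrections`,
#'   `kind`).
#' @export
fret_data <- function(photons, corrections = NULL, kind = c("folding", "binding")) {
  kind <- match.arg(kind)
  photons <- validate_photons(photons)
  allowed <- if (kind == "folding") c("3c", "DA1", "DA2", "Donly") else c("3c/DA1", "DA2", "Donly")
  bad <- setdiff(unique(photons$class), allowed)
  if (length(bad) > 0) {
    stop("segment class(es) ", paste(bad, collapse = ", "), " not allowed in a ",
         kind, " dataset", call. = FALSE)
  }
  structure(list(photons = photons, corrections = corrections, kind = kind),
            class = "fret_data")
}

#' @export
print.fret_data <- function(x, ...) {
  s <- trajectory_rates(x$photons)
  cat("<fret_data> ", x$kind, " experiment: ", nrow(s), " trajectories, ",
      nrow(x$photons), " photons\n", sep = "")
  print(dplyr::count(s, .data$class, wt = .data$n_photons, name = "photons"))
  invisible(x)
}

validate_photons <- function(photons) {
  photons <- tibble::as_tibble(photons)
  req <- c("trajectory_id", "class", "time", "channel")
  miss <- setdiff(req, names(photons))
  if (length(miss) > 0) {
    stop("photon table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_ch <- setdiff(unique(photons$channel), fret_channels)
  if (length(bad_ch) > 0) {
    stop("unknown channel label(s): ", paste(bad_ch, collapse = ", "), call. = FALSE)
  }
  bad_cl <- setdiff(unique(photons$class), fret_classes)
  if (length(bad_cl) > 0) {
    stop("unknown segment class(es): ", paste(bad_cl, collapse = ", "), call. = FALSE)
  }
  unsorted <- photons |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::summarise(ok = all(diff(.data$time) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(unsorted) > 0) {
    stop("arrival times not strictly increasing in trajectory ",
         paste(unsorted$trajectory_id, collapse = ", "), call. = FALSE)
  }
  photons
}

#' Per-trajectory photon count rates
#'
#' Summarises each trajectory: photon count, time span, and the mean count
#' rate n in photons per millisecond. n drives the excitation-dependent
#' dark-entry rate scaling of the blinking models.
#'
#' @param photons A photon table (or a `fret_data`).
#' @return A tibble with one row per trajectory: `trajectory_id`, `class`,
#'   `n_photons`, `span` (s), `rate_ms` (photons per ms).
#' @export
trajectory_rates <- function(photons) {
  if (inherits(photons, "fret_data")) photons <- photons$photons
  photons |>
    dplyr::group_by(.data$trajectory_id, .data$class) |>
    dplyr::summarise(
      n_photons = dplyr::n(),
      span = max(.data$time) - min(.data$time),
      .groups = "drop"
    ) |>
    dplyr::mutate(rate_ms = ifelse(.data$span > 0, .data$n_photons / (.data$span * 1e3), NA_real_))
}

#' Merge detection channels of two-color segments
#'
#' In DA1 segments the photons detected in the A2 channel are mostly A1 leak,
#' so they are combined with A1 (`"DA1-merge"`: A2 -> A1). In DA2 segments the
#' donor and A1 photons are combined and treated as donor photons
#' (`"DA2-merge"`: A1 -> D). Arrival times are unchanged.
#'
#' @param photons Photon table whose rows all belong to the matching class
#'   (`DA1` for `"DA1-merge"`, `DA2` for `"DA2-merge"`).
#' @param scheme `"DA1-merge"` or `"DA2-merge"`.
#' @return The photon table with channels relabelled.
#' @export
combine_channels <- function(photons, scheme = c("DA1-merge", "DA2-merge")) {
  scheme <- match.arg(scheme)
  photons <- tibble::as_tibble(photons)
  need <- if (scheme == "DA1-merge") "DA1" else "DA2"
  if (!all(photons$class == need)) {
    stop(scheme, " applies only to class ", need, " segments", call. = FALSE)
  }
  if (scheme == "DA1-merge") {
    photons$channel[photons$channel == "A2"] <- "A1"
  } else {
    photons$channel[photons$channel == "A1"] <- "D"
  }
  photons
}

#' Bin a photon trajectory into per-channel counts
#'
#' Counts photons per channel in half-open bins `[k*bin_time, (k+1)*bin_time)`
#' measured from each trajectory's first photon. Total counts are conserved.
#'
#' @param photons Photon table.
#' @param bin_time Bin width in seconds (e.g. `1e-3` for the 1 ms bins used
#'   for display histograms).
#' @return A tibble with columns `trajectory_id`, `class`, `bin`, `t_mid`,
#'   `D`, `A1`, `A2`, `n`.
#' @export
bin_trajectory <- function(photons, bin_time) {
  stopifnot(bin_time > 0)
  photons <- tibble::as_tibble(photons)
  if (nrow(photons) == 0) {
    return(tibble::tibble(trajectory_id = character(), class = character(),
                          bin = integer(), t_mid = double(),
                          D = integer(), A1 = integer(), A2 = integer(), n = integer()))
  }
  photons |>
    dplyr::group_by(.data$trajectory_id, .data$class) |>
    dplyr::mutate(bin = as.integer(floor(.data$time / bin_time))) |>
    dplyr::count(.data$bin, .data$channel) |>
    tidyr::pivot_wider(names_from = "channel", values_from = "n", values_fill = 0L) |>
    dplyr::ungroup()  |>
    (\(d) {
      for (ch in fret_channels) if (!ch %in% names(d)) d[[ch]] <- 0L
      d
    })() |>
    dplyr::mutate(t_mid = (.data$bin + 0.5) * bin_time,
                  n = .data$D + .data$A1 + .data$A2) |>
    dplyr::select("trajectory_id", "class", "bin", "t_mid", "D", "A1", "A2", "n") |>
    dplyr::arrange(.data$trajectory_id, .data$bin)
}

# ---- on-disk formats --------------------------------------------------------

time_unit_factor <- function(unit) {
  switch(unit,
         s = 1, ms = 1e-3, us = 1e-6, ns = 1e-9,
         stop("unknown time unit: ", unit, call. = FALSE))
}

#' Read photon trajectories
#'
#' Reads the plain columnar text dialect: one file holds any number of
#' trajectories, each introduced by header lines
#' `#trajectory_id=...`, `#class=...`, `#time_unit=s`, followed by two
#' tab-separated columns (time, integer channel code 0 = D, 1 = A1, 2 = A2).
#' Times are converted to seconds regardless of the declared on-disk unit.
#'
#' A Photon-HDF5 dialect is part of the interface but requires an HDF5
#' binding, which this build does not link against; requesting it raises an
#' informative error.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"photon-hdf5"`.
#' @param corrections,kind Passed to [fret_data()].
#' @return A [fret_data()] object.
#' @export
read_trajectories <- function(path, dialect = c("tsv", "photon-hdf5"),
                              corrections = NULL, kind = c("folding", "binding")) {
  dialect <- match.arg(dialect)
  if (dialect == "photon-hdf5") {
    stop("the photon-hdf5 dialect requires an HDF5 binding, which is not ",
         "available in this build; use the tsv dialect", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^#", lines)
  # group records: a new trajectory starts at each '#trajectory_id=' line
  starts <- grep("^#trajectory_id=", lines)
  if (length(starts) == 0) {
    return(fret_data(tibble::tibble(trajectory_id = character(), class = character(),
                                    time = double(), channel = character()),
                     corrections = corrections, kind = match.arg(kind)))
  }
  ends <- c(starts[-1] - 1L, length(lines))
  parts <- purrr::map2(starts, ends, function(a, b) {
    block <- lines[a:b]
    heads <- block[grepl("^#", block)]
    body <- block[!grepl("^#", block)]
    get <- function(key, default = NULL) {
      m <- grep(paste0("^#", key, "="), heads, value = TRUE)
      if (length(m) == 0) {
        if (is.null(default)) stop("missing header #", key, "= in ", path, call. = FALSE)
        return(default)
      }
      sub(paste0("^#", key, "="), "", m[1])
    }
    id <- get("trajectory_id")
    cls <- get("class")
    unit <- get("time_unit", "s")
    if (length(body) == 0) {
      return(tibble::tibble(trajectory_id = character(), class = character(),
                            time = double(), channel = character()))
    }
    m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    if (ncol(m) != 2) stop("malformed photon record in trajectory ", id, call. = FALSE)
    code <- suppressWarnings(as.integer(m[, 2]))
    if (anyNA(code) || any(code < 0 | code > 2)) {
      stop("unknown channel code in trajectory ", id, call. = FALSE)
    }
    tm <- as.numeric(m[, 1]) * time_unit_factor(unit)
    if (any(diff(tm) <= 0)) {
      stop("arrival times not strictly increasing in trajectory ", id, call. = FALSE)
    }
    tibble::tibble(trajectory_id = id, class = cls, time = tm,
                   channel = fret_channels[code + 1L])
  })
  fret_data(dplyr::bind_rows(parts), corrections = corrections, kind = match.arg(kind))
}

#' Write photon trajectories
#'
#' Writes the TSV dialect read by [read_trajectories()]. Times are written in
#' seconds with full precision (`%.15g`), so a write/read round trip is
#' lossless to well below 1e-12 s.
#'
#' @param data A `fret_data` or a photon table.
#' @param path Output file path.
#' @param dialect Only `"tsv"` is supported in this build.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(data, path, dialect = c("tsv", "photon-hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "photon-hdf5") {
    stop("the photon-hdf5 dialect requires an HDF5 binding, which is not ",
         "available in this build; use the tsv dialect", call. = FALSE)
  }
  photons <- if (inherits(data, "fret_data")) data$photons else validate_photons(data)
  con <- file(path, "w")
  on.exit(close(con))
  ids <- unique(photons$trajectory_id)
  for (id in ids) {
    tr <- photons[photons$trajectory_id == id, ]
    writeLines(c(paste0("#trajectory_id=", id),
                 paste0("#class=", tr$class[1]),
                 "#time_unit=s"), con)
    code <- match(tr$channel, fret_channels) - 1L
    writeLines(sprintf("%.15g\t%d", tr$time, code), con)
  }
  invisible(path)
}
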