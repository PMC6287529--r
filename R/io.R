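is_zip_file <- function(path) {
  magic <- readBin(path, "raw", n = 4)
  length(magic) == 4 &&
    identical(magic[1:2], as.raw(c(0x50, 0x4b))) &&
    magic[3] %in% as.raw(c(0x03, 0x05, 0x07))
}

# Plate positions in RDML are commonly stored as integer react ids
# (row-major over 12 columns on a 96-well plate); map those to "A01" style.
react_id_to_well <- function(id, n_cols = 12) {
  if (grepl("^[0-9]+$", id)) {
    pos <- as.integer(id)
    if (pos >= 1 && pos <= 8 * n_cols) {
      row <- (pos - 1) %/% n_cols + 1
      col <- (pos - 1) %% n_cols + 1
      return(sprintf("%s%02d", LETTERS[row], col))
    }
  }
  id
}

#' Read amplification curves from an RDML file
#'
#' RDML (Real-time PCR Data Markup Language) is the XML interchange format
#' for qPCR experiments, usually shipped as a ZIP archive wrapping one XML
#' document. This reader accepts both the zipped and the bare-XML form and
#' tolerates the v1.1 and v1.2 schema namespaces: amplification data are
#' located structurally (`react` elements holding `adp` data points with
#' `cyc`/`fluor` children), not by namespace URI.
#'
#' One curve is emitted per (react, target) pair — hook detection is per
#' trace — with `well_id` derived from the react identifier (integer plate
#' positions become `"A01"`-style labels) and suffixed with the target name
#' when a react carries more than one target. Data points are sorted by
#' cycle; reacts without data points are skipped with a warning.
#'
#' @param path Path to a `.rdml` (zip) or bare RDML XML file.
#' @return An [amp_curves()] tibble.
#' @export
read_rdml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  xml_path <- path
  if (is_zip_file(path)) {
    exdir <- tempfile("rdml_unzip")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE))
    files <- utils::unzip(path, exdir = exdir)
    xml_files <- files[grepl("\\.(xml|rdml)$", files, ignore.case = TRUE)]
    if (length(xml_files) == 0) xml_files <- files
    if (length(xml_files) == 0) {
      stop("not an RDML file (empty archive): ", path, call. = FALSE)
    }
    xml_path <- xml_files[1]
  }
  doc <- tryCatch(
    xml2::read_xml(xml_path),
    error = function(e) {
      stop("not an RDML file (neither ZIP nor XML): ", path, call. = FALSE)
    }
  )
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "rdml") {
    stop("not an RDML document (root element is not <rdml>): ", path, call. = FALSE)
  }
  reacts <- xml2::xml_find_all(doc, ".//run/react")
  if (length(reacts) == 0) {
    stop(
      "RDML document contains no run/react elements (valid but empty): ", path,
      call. = FALSE
    )
  }
  rows <- purrr::map(reacts, function(react) {
    react_id <- xml2::xml_attr(react, "id")
    well <- react_id_to_well(react_id)
    sample <- xml2::xml_attr(xml2::xml_find_first(react, "./sample"), "id")
    data_nodes <- xml2::xml_find_all(react, "./data")
    multi <- length(data_nodes) > 1
    purrr::map(data_nodes, function(d) {
      target <- xml2::xml_attr(xml2::xml_find_first(d, "./tar"), "id")
      adp <- xml2::xml_find_all(d, "./adp")
      if (length(adp) == 0) {
        warning("react ", react_id, " has no amplification data points; skipped.",
          call. = FALSE
        )
        return(NULL)
      }
      cyc <- xml2::xml_double(xml2::xml_find_all(adp, "./cyc"))
      fluor <- xml2::xml_double(xml2::xml_find_all(adp, "./fluor"))
      ord <- order(cyc)
      tibble::tibble(
        well_id = if (multi && !is.na(target)) paste0(well, "_", target) else well,
        sample_name = sample %||% NA_character_,
        detector = target %||% NA_character_,
        cycle = cyc[ord],
        fluorescence = fluor[ord]
      )
    })
  })
  out <- purrr::list_rbind(purrr::list_flatten(rows))
  if (nrow(out) == 0) {
    stop("RDML document contains reacts but no data points: ", path, call. = FALSE)
  }
  amp_curves(out)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read a wide CSV plate of amplification curves
#'
#' Expects a header row, one cycle column and one fluorescence column per
#' well (`well_id` = column header). Trailing missing cells in a well's
#' column are trimmed (shorter runs); a missing cell in the interior of a
#' series is an error, as is any non-numeric cell.
#'
#' @param path Path to the delimited file.
#' @param cycle_column Name of the cycle column (default: the first
#'   column).
#' @return An [amp_curves()] tibble (possibly empty, with a warning, when
#'   only the cycle column is present).
#' @export
read_csv_plate <- function(path, cycle_column = NULL) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    name_repair = "minimal", progress = FALSE
  )
  if (anyDuplicated(names(raw))) {
    stop(
      "duplicate column header(s): ",
      paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(cycle_column)) cycle_column <- names(raw)[1]
  if (!cycle_column %in% names(raw)) {
    stop("cycle column '", cycle_column, "' not found.", call. = FALSE)
  }
  to_num <- function(col, colname) {
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad) > 0) {
      stop(
        "non-numeric value '", col[bad[1]], "' at row ", bad[1],
        ", column '", colname, "'.",
        call. = FALSE
      )
    }
    num
  }
  cycles <- to_num(raw[[cycle_column]], cycle_column)
  wells <- setdiff(names(raw), cycle_column)
  if (length(wells) == 0) {
    warning("no fluorescence columns found; returning an empty curve set.", call. = FALSE)
    return(amp_curves(tibble::tibble(
      well_id = character(), cycle = numeric(), fluorescence = numeric()
    )))
  }
  out <- purrr::map(wells, function(w) {
    y <- to_num(raw[[w]], w)
    n_keep <- max(c(0L, which(!is.na(y))))
    if (n_keep == 0L) {
      warning("well '", w, "' is entirely empty; skipped.", call. = FALSE)
      return(NULL)
    }
    y <- y[seq_len(n_keep)]
    interior_na <- which(is.na(y))
    if (length(interior_na) > 0) {
      stop(
        "missing value in the interior of well '", w, "' at row ", interior_na[1],
        " (only trailing cells may be empty).",
        call. = FALSE
      )
    }
    tibble::tibble(well_id = w, cycle = cycles[seq_len(n_keep)], fluorescence = y)
  })
  amp_curves(purrr::list_rbind(out))
}

#' Write amplification curves as a wide CSV plate
#'
#' Inverse of [read_csv_plate()]: first column `cycle`, one column per
#' well. Wells shorter than the longest leave trailing cells empty.
#'
#' @param curves An [amp_curves()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_plate <- function(curves, path) {
  curves <- amp_curves(curves)
  wide <- curves |>
    dplyr::select("well_id", "cycle", "fluorescence") |>
    tidyr::pivot_wider(names_from = "well_id", values_from = "fluorescence") |>
    dplyr::arrange(.data$cycle)
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read human hook ratings
#'
#' Two-column delimited text mapping `well_id` to a rating: `y` (hook) or
#' `n` (no hook), case-insensitive; `hook`/`no_hook` are also accepted. A
#' header row (`well_id,label` or similar) is tolerated.
#'
#' @param path Path to the ratings file.
#' @return A tibble `well_id`, `label` with labels normalized to
#'   `"hook"`/`"no_hook"`; empty tibble for an empty file.
#' @export
read_labels <- function(path) {
  raw <- readr::read_csv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble::tibble(well_id = character(), label = character()))
  }
  if (ncol(raw) < 2) stop("expected two columns: well_id, label.", call. = FALSE)
  # tolerate a header row
  if (tolower(raw[[2]][1]) %in% c("label", "rating", "hook")) raw <- raw[-1, ]
  norm <- c(
    y = "hook", n = "no_hook", hook = "hook", no_hook = "no_hook"
  )[tolower(raw[[2]])]
  bad <- which(is.na(norm))
  if (length(bad) > 0) {
    stop(
      "invalid label '", raw[[2]][bad[1]], "' for well '", raw[[1]][bad[1]],
      "' (row ", bad[1], "): expected y or n.",
      call. = FALSE
    )
  }
  tibble::tibble(well_id = raw[[1]], label = unname(norm))
}

#' Write hook ratings
#'
#' @param labels Tibble with `well_id` and `label`
#'   (`"hook"`/`"no_hook"`).
#' @param path Output path; written as `well_id,label` rows with `y`/`n`
#'   codes, readable by [read_labels()].
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  out <- tibble::tibble(
    well_id = labels$well_id,
    label = ifelse(labels$label == "hook", "y", "n")
  )
  readr::write_csv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a minimal RDML file (fixture writer)
#'
#' Serializes curves into a minimal RDML v1.2 document — one `react` per
#' well with `adp` data points — either as bare XML or wrapped in a stored
#' (uncompressed) ZIP archive, the container real instruments emit. Only
#' the elements this package reads are written; this is a fixture/testing
#' utility, not an RDML editor.
#'
#' @param curves An [amp_curves()] table.
#' @param path Output path.
#' @param zip Wrap the XML in a ZIP container (default FALSE). Requires
#'   the `digest` package (for the archive checksum).
#' @return `path`, invisibly.
#' @export
write_rdml <- function(curves, path, zip = FALSE) {
  curves <- amp_curves(curves)
  wells <- split_wells(curves)
  reacts <- purrr::imap_chr(wells, function(df, w) {
    adp <- paste0(
      sprintf(
        "      <adp><cyc>%.15g</cyc><fluor>%.15g</fluor></adp>",
        df$cycle, df$fluorescence
      ),
      collapse = "\n"
    )
    tar <- df$detector[1]
    if (is.na(tar)) tar <- "target1"
    sample <- df$sample_name[1]
    if (is.na(sample)) sample <- w
    paste0(
      "   <react id=\"", w, "\">\n",
      "    <sample id=\"", sample, "\"/>\n",
      "    <data>\n",
      "     <tar id=\"", tar, "\"/>\n",
      adp, "\n",
      "    </data>\n",
      "   </react>"
    )
  })
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<rdml xmlns=\"http://www.rdml.org\" version=\"1.2\">\n",
    " <experiment id=\"exp1\">\n",
    "  <run id=\"run1\">\n",
    paste0(reacts, collapse = "\n"), "\n",
    "  </run>\n",
    " </experiment>\n",
    "</rdml>\n"
  )
  if (!zip) {
    writeLines(xml, path)
    return(invisible(path))
  }
  writeBin(make_stored_zip("rdml_data.xml", charToRaw(xml)), path)
  invisible(path)
}

uint_le <- function(x, n_bytes) {
  bytes <- raw(n_bytes)
  for (i in seq_len(n_bytes)) {
    bytes[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  bytes
}

# Minimal single-file ZIP archive, method 0 (stored). Enough container for
# RDML readers; avoids an external `zip` binary.
make_stored_zip <- function(fname, data) {
  if (!requireNamespace("digest", quietly = TRUE)) {
    stop("writing zipped RDML requires the 'digest' package.", call. = FALSE)
  }
  crc_hex <- digest::digest(data, algo = "crc32", serialize = FALSE)
  crc_hex <- formatC(crc_hex, width = 8, flag = "0")
  # parse in two 16-bit halves: a full 32-bit CRC can overflow strtoi()
  crc <- strtoi(substr(crc_hex, 1, 4), base = 16L) * 65536 +
    strtoi(substr(crc_hex, 5, 8), base = 16L)
  name_raw <- charToRaw(fname)
  sz <- length(data)
  local_header <- c(
    uint_le(0x04034b50, 4), uint_le(20, 2), uint_le(0, 2), uint_le(0, 2),
    uint_le(0, 2), uint_le(0, 2), uint_le(crc, 4), uint_le(sz, 4),
    uint_le(sz, 4), uint_le(length(name_raw), 2), uint_le(0, 2), name_raw
  )
  central <- c(
    uint_le(0x02014b50, 4), uint_le(20, 2), uint_le(20, 2), uint_le(0, 2),
    uint_le(0, 2), uint_le(0, 2), uint_le(0, 2), uint_le(crc, 4),
    uint_le(sz, 4), uint_le(sz, 4), uint_le(length(name_raw), 2),
    uint_le(0, 2), uint_le(0, 2), uint_le(0, 2), uint_le(0, 2),
    uint_le(0, 4), uint_le(0, 4), name_raw
  )
  eocd <- c(
    uint_le(0x06054b50, 4), uint_le(0, 2), uint_le(0, 2), uint_le(1, 2),
    uint_le(1, 2), uint_le(length(central), 4),
    uint_le(length(local_header) + sz, 4), uint_le(0, 2)
  )
  c(local_header, data, central, eocd)
}
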