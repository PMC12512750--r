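# Minimal two-port Touchstone (.s2p) reader/writer.
#
# Supported on read: DB (dB/angle) and RI (real/imaginary) formats, HZ/KHZ/
# MHZ/GHZ frequency units, '!' comments, one standard option line. Written
# files are always "# GHZ S DB R 50" with angles in degrees. Angles are
# written from the unwrapped internal phases without re-wrapping so that a
# write/read cycle is numerically lossless; the reader unwraps along
# frequency regardless, so wrapped files from other tools are handled too.

write_touchstone <- function(path, freq_ghz, sxx_mag, sxx_phase,
                             sxy_mag, sxy_phase, comment = NULL) {
  deg <- function(rad) rad * 180 / pi
  header <- c(
    if (!is.null(comment)) paste0("! ", comment),
    "! 2-port S-parameter sweep (dB / unwrapped degrees)",
    "# GHZ S DB R 50"
  )
  data <- cbind(freq_ghz,
                sxx_mag, deg(sxx_phase),   # S11
                sxy_mag, deg(sxy_phase),   # S21
                sxy_mag, deg(sxy_phase),   # S12 (reciprocal)
                sxx_mag, deg(sxx_phase))   # S22 (symmetric device)
  lines <- apply(data, 1, function(r) paste(sprintf("%.12g", r),
                                            collapse = " "))
  writeLines(c(header, lines), path)
  invisible(path)
}

read_touchstone <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Touchstone file not found: %s", path),
          class = "icp_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  unit_scale <- 1e-9   # default per Touchstone spec: Hz -> GHz... (GHz = 1)
  fmt <- "MA"
  unit <- "GHZ"
  seen_option <- FALSE
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- sub("!.*$", "", lines[[i]])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      if (seen_option) next  # later option lines are ignored per spec
      toks <- toupper(strsplit(trimws(sub("^#", "", ln)), "\\s+")[[1]])
      unit <- if (length(toks) >= 1) toks[[1]] else "GHZ"
      if ("DB" %in% toks) fmt <- "DB"
      else if ("RI" %in% toks) fmt <- "RI"
      else if ("MA" %in% toks) fmt <- "MA"
      seen_option <- TRUE
      next
    }
    vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(vals) != 9 || anyNA(vals)) {
      abort(sprintf("Malformed Touchstone data at %s line %d.", path, i),
            class = "icp_parse_error")
    }
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows)) {
    abort(sprintf("No data rows in Touchstone file %s.", path),
          class = "icp_parse_error")
  }
  m <- do.call(rbind, rows)
  scale <- switch(unit, HZ = 1e-9, KHZ = 1e-6, MHZ = 1e-3, GHZ = 1,
                  abort(sprintf("Unsupported frequency unit '%s' in %s.",
                                unit, path), class = "icp_parse_error"))
  freq <- m[, 1] * scale
  to_db_ang <- function(a, b) {
    if (fmt == "DB") {
      list(mag = a, phase = b * pi / 180)
    } else if (fmt == "RI") {
      z <- complex(real = a, imaginary = b)
      list(mag = 20 * log10(Mod(z)), phase = Arg(z))
    } else {  # MA: linear magnitude / angle in degrees
      list(mag = 20 * log10(a), phase = b * pi / 180)
    }
  }
  s11 <- to_db_ang(m[, 2], m[, 3])
  s21 <- to_db_ang(m[, 4], m[, 5])
  list(freq_ghz = freq,
       sxx_mag = s11$mag, sxx_phase = unwrap_phase(s11$phase),
       sxy_mag = s21$mag, sxy_phase = unwrap_phase(s21$phase))
}
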