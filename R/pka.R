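.aa1 <- setNames(names(.aa3), unname(.aa3))

#' Parse PROPKA 3.1 summary output files
#'
#' Reads the `SUMMARY OF THIS PREDICTION` table of one PROPKA 3.1 file per
#' frame into one record per titratable residue per frame, and the coupled-
#' residues block (two alternative pKa values per coupled group: in
#' alternative a this group is protonated first and stabilised by the
#' partner, in alternative b the roles are reversed; the a/b labels are
#' preserved from the file, never inferred). Residues absent from a frame
#' are simply absent from the records, not imputed.
#'
#' @param files character vector of `.pka` file paths, one per frame.
#' @param frame_ids optional frame ids (default `0..n-1` in file order).
#' @return data.frame with columns `frame`, `residue` (one-letter + number,
#'   e.g. `"D308"`), `pka`, `coupled`, `partner`, `alt_a`, `alt_b`.
#' @export
parse_propka <- function(files, frame_ids = NULL) {
  if (is.null(frame_ids)) frame_ids <- seq_along(files) - 1L
  recs <- vector("list", length(files))
  for (fi in seq_along(files)) {
    lines <- readLines(files[fi])
    isum <- grep("^SUMMARY OF THIS PREDICTION", lines)
    if (length(isum) != 1L)
      stop_("%s: no SUMMARY OF THIS PREDICTION section found", files[fi])
    res <- character(0); pka <- numeric(0)
    i <- isum + 1L
    pat <- "^\\s+([A-Z]{3})\\s+(\\d+)\\s+\\S+\\s+(-?[0-9.]+)"
    while (i <= length(lines)) {
      ln <- lines[i]
      if (grepl("^-{5,}", ln)) break
      m <- regmatches(ln, regexec(pat, ln))[[1]]
      if (length(m) == 4L) {
        aa1 <- .aa1[m[2]]
        if (is.na(aa1)) stop_("%s line %d: unknown residue '%s'", files[fi], i, m[2])
        res <- c(res, paste0(aa1, m[3]))
        pka <- c(pka, as.numeric(m[4]))
      } else if (grepl("[A-Z]{3}", ln) && !grepl("Group", ln)) {
        stop_("%s: malformed summary line %d: '%s'", files[fi], i, ln)
      }
      i <- i + 1L
    }
    df <- data.frame(frame = frame_ids[fi], residue = res, pka = pka,
                     coupled = FALSE, partner = NA_character_,
                     alt_a = NA_real_, alt_b = NA_real_)
    ic <- grep("is coupled to", lines)
    for (cl in ic) {
      m <- regmatches(lines[cl],
                      regexec("^\\s*([A-Z]{3})\\s+(\\d+)\\s+\\S+ is coupled to ([A-Z]{3})\\s+(\\d+)", lines[cl]))[[1]]
      if (length(m) != 5L) stop_("%s line %d: malformed coupling line", files[fi], cl)
      rid <- paste0(.aa1[m[2]], m[3])
      pid <- paste0(.aa1[m[4]], m[5])
      row <- which(df$residue == rid)
      if (length(row) != 1L)
        stop_("%s line %d: coupled residue %s not in summary", files[fi], cl, rid)
      getalt <- function(tag) {
        ln <- lines[cl + if (tag == "a") 1L else 2L]
        mm <- regmatches(ln, regexec(sprintf("Alternative %s pKa .* (-?[0-9.]+)\\s*$", tag), ln))[[1]]
        if (length(mm) != 2L)
          stop_("%s line %d: missing alternative %s pKa", files[fi], cl, tag)
        as.numeric(mm[2])
      }
      df$coupled[row] <- TRUE
      df$partner[row] <- pid
      df$alt_a[row] <- getalt("a")
      df$alt_b[row] <- getalt("b")
    }
    recs[[fi]] <- df
  }
  do.call(rbind, recs)
}

#' Aggregate ensemble pKa records per residue
#'
#' For each residue: mean and SD over all frames, mean and SD over coupling
#' frames only, the percentage of coupling frames, the fraction of the
#' distribution inside the critical window (default pH 6--7, the range over
#' which a group can act as a physiological pH sensor), and normalised
#' histograms of all values plus -- when any coupling is present -- of the
#' alternative-a and alternative-b values.
#'
#' "The distribution reaches into the window" is operationalised as window
#' mass above `window_threshold` (default 1%).
#'
#' @param records data.frame from [parse_propka()] or
#'   [generate_pka_records()].
#' @param window critical pKa window `c(lo, hi)`.
#' @param window_threshold minimum window mass that counts as "reaching
#'   into" the window.
#' @param breaks histogram bin edges (default 0.25-unit bins spanning the
#'   data).
#' @return object of class `pka_summary`: data.frame `table` with one row
#'   per residue and an attribute-free list `histograms` per residue.
#' @export
aggregate_pka <- function(records, window = c(6, 7), window_threshold = 0.01,
                          breaks = NULL) {
  if (nrow(records) == 0L) stop_("no records")
  resids <- unique(records$residue)
  rows <- list(); hists <- list()
  for (rid in resids) {
    r <- records[records$residue == rid, ]
    cp <- r[r$coupled, ]
    vals <- r$pka
    if (is.null(breaks)) {
      lo <- floor(min(c(vals, cp$alt_a, cp$alt_b), na.rm = TRUE) * 4) / 4
      hi <- ceiling(max(c(vals, cp$alt_a, cp$alt_b), na.rm = TRUE) * 4) / 4
      if (hi <= lo) hi <- lo + 0.25
      bk <- seq(lo, hi, by = 0.25)
    } else bk <- breaks
    h_all <- hist(vals, breaks = bk, plot = FALSE)
    hl <- list(all = h_all)
    if (nrow(cp) > 0) {
      hl$alt_a <- hist(cp$alt_a, breaks = bk, plot = FALSE)
      hl$alt_b <- hist(cp$alt_b, breaks = bk, plot = FALSE)
    }
    hists[[rid]] <- hl
    in_window <- mean(vals >= window[1] & vals <= window[2])
    rows[[rid]] <- data.frame(
      residue = rid, n_frames = nrow(r),
      mean = mean(vals), sd = if (nrow(r) > 1) sd(vals) else 0,
      mean_coupled = if (nrow(cp) > 0) mean(cp$pka) else NA_real_,
      sd_coupled = if (nrow(cp) > 1) sd(cp$pka) else
        if (nrow(cp) == 1) 0 else NA_real_,
      mean_alt_a = if (nrow(cp) > 0) mean(cp$alt_a) else NA_real_,
      mean_alt_b = if (nrow(cp) > 0) mean(cp$alt_b) else NA_real_,
      coupling_percent = 100 * nrow(cp) / nrow(r),
      window_fraction = in_window,
      reaches_window = in_window > window_threshold)
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 histograms = hists, window = window,
                 window_threshold = window_threshold),
            class = "pka_summary")
}

#' @export
print.pka_summary <- function(x, ...) {
  cat(sprintf("<pka_summary> %d residue(s), window [%g, %g]\n",
              nrow(x$table), x$window[1], x$window[2]))
  print(x$table[, c("residue", "n_frames", "mean", "sd", "coupling_percent",
                    "window_fraction", "reaches_window")], row.names = FALSE)
  invisible(x)
}
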