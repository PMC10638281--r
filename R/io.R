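# Chromatogram IO and summary reporting.
#
# The native chromatogram format is a long CSV (channel_id, time_min,
# intensity), one block of monotone times per channel.  An mzML dialect is
# also supported: the package writes a minimal chromatogram-list mzML
# (64-bit floats, no compression) and reads mzML through the mzR package
# when installed, so either dialect yields identical traces.

#' Write MRM chromatograms as a long CSV table
#'
#' @param traces list of [mrm_trace] objects.
#' @param path output CSV path (columns `channel_id`, `time_min`,
#'   `intensity`).
#' @return `path`, invisibly.
#' @export
write_chromatograms <- function(traces, path) {
  tab <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(channel_id = tr$channel_id, time_min = tr$time,
               intensity = tr$intensity, stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read MRM chromatograms
#'
#' @param path CSV (long format, see [write_chromatograms()]) or mzML file.
#' @param dialect `"auto"` (by file extension), `"csv"` or `"mzml"`.
#' @param transitions optional transition list; when given, channel ids
#'   absent from it are dropped with a message.
#' @return list of [mrm_trace] objects, one per channel, in file order.
#' @export
read_chromatograms <- function(path, dialect = c("auto", "csv", "mzml"),
                               transitions = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "csv"
  }
  if (dialect == "mzml") {
    traces <- read_chromatograms_mzml(path)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    needed <- c("channel_id", "time_min", "intensity")
    if (!all(needed %in% names(tab))) {
      stop("chromatogram table needs columns ", paste(needed, collapse = ", "))
    }
    ids <- unique(tab$channel_id)
    traces <- lapply(ids, function(id) {
      rows <- which(tab$channel_id == id)
      tt <- tab$time_min[rows]
      bad <- which(diff(tt) <= 0)
      if (length(bad)) {
        stop("non-monotone time for channel ", id, " at file row ",
             rows[bad[1] + 1L] + 1L)  # +1 for the header line
      }
      mrm_trace(id, tt, tab$intensity[rows])
    })
  }
  if (!is.null(transitions)) {
    known <- unique(paste(transitions$compound, transitions$channel, sep = "|"))
    keep <- vapply(traces, function(tr) tr$channel_id %in% known, logical(1))
    if (any(!keep)) {
      message("dropping ", sum(!keep), " trace(s) with unknown channel ids")
    }
    traces <- traces[keep]
  }
  traces
}

# ---- minimal chromatogram-list mzML ---------------------------------------

.encode_doubles <- function(x) {
  # single-line base64: mzML readers reject embedded line breaks
  gsub("[\r\n]", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8, endian = "little")))
}

#' Write chromatograms as a minimal mzML file
#'
#' Emits an mzML document whose chromatogramList holds one chromatogram
#' per MRM channel (time in minutes, 64-bit float arrays, uncompressed).
#' Readable by common mzML readers (e.g. mzR) and by
#' [read_chromatograms_mzml()].
#'
#' @param traces list of [mrm_trace] objects.
#' @param path output path (conventionally `.mzML`).
#' @return `path`, invisibly.
#' @export
write_chromatograms_mzml <- function(traces, path) {
  cv <- function(node, acc, name, value = NULL, unit = NULL) {
    p <- xml2::xml_add_child(node, "cvParam", cvRef = "MS", accession = acc,
                             name = name)
    if (!is.null(value)) xml2::xml_set_attr(p, "value", value)
    if (!is.null(unit)) {
      xml2::xml_set_attr(p, "unitCvRef", "UO")
      xml2::xml_set_attr(p, "unitAccession", unit[1])
      xml2::xml_set_attr(p, "unitName", unit[2])
    }
    p
  }
  doc <- xml2::xml_new_root(
    "mzML",
    xmlns = "http://psi.hupo.org/ms/mzml",
    version = "1.1.0"
  )
  cvl <- xml2::xml_add_child(doc, "cvList", count = "2")
  xml2::xml_add_child(cvl, "cv", id = "MS", fullName = "Proteomics Standards Initiative Mass Spectrometry Ontology",
                      URI = "https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo")
  xml2::xml_add_child(cvl, "cv", id = "UO", fullName = "Unit Ontology",
                      URI = "https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo")
  fd <- xml2::xml_add_child(doc, "fileDescription")
  fc <- xml2::xml_add_child(fd, "fileContent")
  cv(fc, "MS:1001473", "selected reaction monitoring chromatogram")
  sl <- xml2::xml_add_child(doc, "softwareList", count = "1")
  xml2::xml_add_child(sl, "software", id = "cilfahfa", version = "0.1.0")
  icl <- xml2::xml_add_child(doc, "instrumentConfigurationList", count = "1")
  ic <- xml2::xml_add_child(icl, "instrumentConfiguration", id = "IC1")
  cv(ic, "MS:1000031", "instrument model")
  dpl <- xml2::xml_add_child(doc, "dataProcessingList", count = "1")
  dp <- xml2::xml_add_child(dpl, "dataProcessing", id = "DP1")
  pm <- xml2::xml_add_child(dp, "processingMethod", order = "1",
                            softwareRef = "cilfahfa")
  cv(pm, "MS:1000544", "Conversion to mzML")
  run <- xml2::xml_add_child(doc, "run", id = "run1",
                             defaultInstrumentConfigurationRef = "IC1")
  cl <- xml2::xml_add_child(run, "chromatogramList",
                            count = as.character(length(traces)),
                            defaultDataProcessingRef = "DP1")
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    ch <- xml2::xml_add_child(cl, "chromatogram", index = as.character(i - 1L),
                              id = tr$channel_id,
                              defaultArrayLength = as.character(length(tr$time)))
    cv(ch, "MS:1001473", "selected reaction monitoring chromatogram")
    bal <- xml2::xml_add_child(ch, "binaryDataArrayList", count = "2")
    tb <- .encode_doubles(tr$time)
    ba <- xml2::xml_add_child(bal, "binaryDataArray",
                              encodedLength = as.character(nchar(tb)))
    cv(ba, "MS:1000523", "64-bit float")
    cv(ba, "MS:1000576", "no compression")
    cv(ba, "MS:1000595", "time array", unit = c("UO:0000031", "minute"))
    xml2::xml_add_child(ba, "binary", tb)
    ib <- .encode_doubles(tr$intensity)
    ba <- xml2::xml_add_child(bal, "binaryDataArray",
                              encodedLength = as.character(nchar(ib)))
    cv(ba, "MS:1000523", "64-bit float")
    cv(ba, "MS:1000576", "no compression")
    cv(ba, "MS:1000515", "intensity array",
       unit = c("MS:1000131", "number of detector counts"))
    xml2::xml_add_child(ba, "binary", ib)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a chromatogram-list mzML file
#'
#' Uses the mzR package when available (any standards-compliant mzML);
#' otherwise falls back to parsing the uncompressed 64-bit float layout
#' written by [write_chromatograms_mzml()].
#'
#' @param path mzML path.
#' @return list of [mrm_trace] objects.
#' @export
read_chromatograms_mzml <- function(path) {
  if (requireNamespace("mzR", quietly = TRUE)) {
    ms <- mzR::openMSfile(path, backend = "pwiz")
    on.exit(mzR::close(ms))
    hdr <- mzR::chromatogramHeader(ms)
    chroms <- mzR::chromatograms(ms)
    if (is.data.frame(chroms)) chroms <- list(chroms)
    return(lapply(seq_len(nrow(hdr)), function(i) {
      mrm_trace(hdr$chromatogramId[i], chroms[[i]][[1]], chroms[[i]][[2]])
    }))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//chromatogram")
  lapply(nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    decode <- function(a) {
      bytes <- jsonlite::base64_dec(
        xml2::xml_text(xml2::xml_find_first(a, ".//binary")))
      readBin(bytes, what = "numeric", size = 8, n = length(bytes) %/% 8L,
              endian = "little")
    }
    is_time <- vapply(arrays, function(a) {
      length(xml2::xml_find_all(a, ".//cvParam[@accession='MS:1000595']")) > 0
    }, logical(1))
    mrm_trace(id, decode(arrays[is_time][[1]]), decode(arrays[!is_time][[1]]))
  })
}

# ---- reporting ------------------------------------------------------------

#' Write dataset summary table and figure
#'
#' Writes the per-sample counts as `summary.csv` and a figure
#' (`summary.pdf`): bars for family counts with overlaid lines for
#' regioisomer counts and total MS intensity per sample.
#'
#' @param summary a [compile_dataset()] object.
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
report_summary <- function(summary, out_dir) {
  stopifnot(inherits(summary, "dataset_summary"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "summary.csv")
  utils::write.csv(summary$per_sample, csv, row.names = FALSE, quote = FALSE)
  files <- csv
  ps <- summary$per_sample
  if (nrow(ps) == 0L || all(ps$n_regioisomers == 0)) {
    message("empty summary: table written, figure skipped")
    return(invisible(files))
  }
  pdf_path <- file.path(out_dir, "summary.pdf")
  grDevices::pdf(pdf_path, width = max(6, nrow(ps) * 0.6), height = 5)
  on.exit(grDevices::dev.off())
  mids <- graphics::barplot(ps$n_families, names.arg = ps$sample,
                            col = "cyan3", las = 2, cex.names = 0.7,
                            ylim = c(0, max(ps$n_regioisomers) * 1.15),
                            ylab = "count",
                            main = "FAHFA families and regioisomers per sample")
  graphics::lines(mids, ps$n_regioisomers, type = "b", col = "red", pch = 16)
  if (any(ps$total_intensity > 0)) {
    scaled <- ps$total_intensity / max(ps$total_intensity) *
      max(ps$n_regioisomers)
    graphics::lines(mids, scaled, type = "b", col = "darkgreen", pch = 17)
  }
  graphics::legend("topright", bty = "n", cex = 0.8,
                   legend = c("families", "regioisomers", "total intensity (scaled)"),
                   fill = c("cyan3", NA, NA), border = c("black", NA, NA),
                   col = c(NA, "red", "darkgreen"), pch = c(NA, 16, 17),
                   lty = c(NA, 1, 1))
  files <- c(files, pdf_path)
  invisible(files)
}

#' Run the screening + annotation pipeline on one sample
#'
#' Convenience wrapper: screens the traces of one run for light/heavy
#' peak pairs and annotates the candidates by RI matching.
#'
#' @param traces list of [mrm_trace] for the run.
#' @param cal an [fit_ri_calibration()] object.
#' @param predictions prediction table from [expand_predictions()].
#' @param min_height,min_width,snr,rt_tol,ratio_window screening parameters
#'   (see [screen_run()]).
#' @param ri_tol annotation tolerance (see [annotate_by_ri()]).
#' @return annotation record data frame.
#' @export
profile_sample <- function(traces, cal, predictions = expand_predictions(),
                           min_height = 50, min_width = 0.01, snr = 5,
                           rt_tol = 0.05, ratio_window = c(0.5, 2),
                           ri_tol = 10) {
  candidates <- screen_run(traces, min_height = min_height,
                           min_width = min_width, snr = snr, rt_tol = rt_tol,
                           ratio_window = ratio_window)
  annotate_by_ri(candidates, cal, predictions, ri_tol = ri_tol)
}
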