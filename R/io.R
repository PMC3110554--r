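#' Read protein sequences from a FASTA file
#'
#' Thin validating wrapper around [Biostrings::readAAStringSet()]. Record ids
#' are the first whitespace-delimited token of each header; sequences are
#' upper-cased. Duplicate ids, empty records and non-alphabetic residues are
#' rejected with errors naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, id -> residue string.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id '%s' in %s",
                 ids[duplicated(ids)][1], path), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) {
    stop(sprintf("empty record '%s' in %s", ids[empty[1]], path),
         call. = FALSE)
  }
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad)) {
    stop(sprintf("non-alphabetic characters in record '%s' in %s",
                 ids[which(bad)[1]], path), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Read per-residue secondary structure from STRIDE output
#'
#' Parses the `ASG` records of a STRIDE report. A residue is helical only in
#' the alpha-helix state `H`; 3-10 helices (`G`) are not counted as helical
#' by default since many alpha-helices merely begin or end with a short 3-10
#' turn. With `merge_310 = TRUE`, `G` runs immediately adjacent to an `H` run
#' are merged into the neighbouring alpha-helix (sensitivity analysis).
#' Positions are STRIDE's sequential (ordinal) residue numbers, i.e. 1-based
#' positions in the resolved chain.
#'
#' @param path Path to a STRIDE output file.
#' @param chain Chain identifier to keep; required when the file reports
#'   several chains.
#' @param merge_310 Merge leading/trailing 3-10 turns into adjacent
#'   alpha-helices.
#' @return Data frame with columns `position`, `residue` (one-letter),
#'   `code` (STRIDE one-letter state) and `helical`.
#' @export
read_stride <- function(path, chain = NULL, merge_310 = FALSE) {
  lines <- readLines(path, warn = FALSE)
  asg <- grep("^ASG ", lines, value = TRUE)
  if (length(asg) == 0L) {
    stop(sprintf("no ASG records found in %s: not a STRIDE output?", path),
         call. = FALSE)
  }
  f <- strsplit(trimws(asg), "\\s+")
  resname <- vapply(f, `[`, character(1), 2)
  ch <- vapply(f, `[`, character(1), 3)
  ordinal <- as.integer(vapply(f, `[`, character(1), 5))
  code <- vapply(f, `[`, character(1), 6)
  chains <- unique(ch)
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      stop(sprintf("STRIDE file %s reports chains %s; pick one with chain=",
                   path, paste(chains, collapse = ", ")), call. = FALSE)
    }
    chain <- chains
  } else if (!chain %in% chains) {
    stop(sprintf("chain '%s' not in %s (found: %s)", chain, path,
                 paste(chains, collapse = ", ")), call. = FALSE)
  }
  keep <- ch == chain
  out <- data.frame(position = ordinal[keep],
                    residue = unname(three_to_one[resname[keep]]),
                    code = code[keep])
  out <- out[order(out$position), , drop = FALSE]
  out$helical <- out$code == "H"
  if (merge_310) {
    h <- out$helical
    g <- out$code == "G"
    repeat {
      grow <- g & !h &
        (c(FALSE, h[-length(h)]) | c(h[-1], FALSE))
      if (!any(grow)) break
      h[grow] <- TRUE
    }
    out$helical <- h
  }
  rownames(out) <- NULL
  out
}

#' Per-position helical track from a STRIDE table
#'
#' @param stride Output of [read_stride()].
#' @param length Sequence length; defaults to the largest position seen.
#' @return Logical vector of length `length` (FALSE where unreported).
#' @export
stride_helical <- function(stride, length = max(stride$position)) {
  h <- rep(FALSE, length)
  h[stride$position[stride$helical]] <- TRUE
  h
}

#' Read membrane regions from a PDBTM XML file
#'
#' Extracts `REGION` elements (namespaced or not). A residue is in the
#' membrane when covered by a region of type `"H"` (alpha-helical membrane
#' segment); every other region type (loops, re-entrant loops, interfacial
#' segments...) maps to not-in-membrane. Coordinates are the `seq_beg`/
#' `seq_end` sequential positions.
#'
#' @param path Path to a PDBTM XML file.
#' @param chain Optional chain id filter (matches the CHAIN element's
#'   `CHAINID`).
#' @return Data frame with columns `chain`, `seq_beg`, `seq_end`, `type`.
#' @export
read_pdbtm <- function(path, chain = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("malformed XML in %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  ch_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='CHAIN']")
  rows <- list()
  for (cn in ch_nodes) {
    cid <- xml2::xml_attr(cn, "CHAINID")
    regs <- xml2::xml_find_all(cn, ".//*[local-name()='REGION']")
    for (rg in regs) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = cid,
        seq_beg = as.integer(xml2::xml_attr(rg, "seq_beg")),
        seq_end = as.integer(xml2::xml_attr(rg, "seq_end")),
        type = xml2::xml_attr(rg, "type")
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), seq_beg = integer(),
               seq_end = integer(), type = character())
  if (!is.null(chain)) {
    if (!chain %in% out$chain) {
      stop(sprintf("chain '%s' not in %s (found: %s)", chain, path,
                   paste(unique(out$chain), collapse = ", ")), call. = FALSE)
    }
    out <- out[out$chain == chain, , drop = FALSE]
  }
  if (!any(out$type == "H")) {
    warning(sprintf("no alpha-helical membrane region (type H) in %s", path))
  }
  rownames(out) <- NULL
  out
}

#' Per-position membrane track from a PDBTM region table
#'
#' @param regions Output of [read_pdbtm()].
#' @param length Sequence length; defaults to the largest `seq_end`.
#' @return Logical vector: TRUE inside type-`H` regions.
#' @export
pdbtm_membrane <- function(regions, length = max(regions$seq_end, 0L)) {
  m <- rep(FALSE, length)
  h <- regions[regions$type == "H", , drop = FALSE]
  for (i in seq_len(nrow(h))) m[h$seq_beg[i]:h$seq_end[i]] <- TRUE
  m
}

#' Read / write the per-residue annotation TSV
#'
#' The canonical exchange format: tab-separated columns `sequence_id`,
#' `position` (1-based, contiguous `1..L` per sequence), `residue`,
#' `helical` (0/1), `in_membrane` (0/1). Write-then-read is the identity.
#'
#' @param path TSV file path.
#' @param kinks Optional named list (per sequence id) of kink positions to
#'   attach to the annotations.
#' @return Named list, one element per sequence: list with `annotation`
#'   (a `membrane_annotation`) and `sequence` (residue string).
#' @export
read_annotation_tsv <- function(path, kinks = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "position", "residue", "helical", "in_membrane")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("annotation TSV %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- list()
  for (id in unique(df$sequence_id)) {
    sub <- df[df$sequence_id == id, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    expect <- seq_len(nrow(sub))
    if (!identical(as.integer(sub$position), expect)) {
      gap <- expect[which(as.integer(sub$position) != expect)[1]]
      stop(sprintf("positions of '%s' are not contiguous 1..L: problem at position %d",
                   id, gap), call. = FALSE)
    }
    out[[id]] <- list(
      annotation = membrane_annotation(
        helical = as.logical(sub$helical),
        in_membrane = as.logical(sub$in_membrane),
        kinks = if (!is.null(kinks)) kinks[[id]] else integer(),
        sequence_id = id
      ),
      sequence = paste(sub$residue, collapse = "")
    )
  }
  out
}

#' @rdname read_annotation_tsv
#' @param annotation A `membrane_annotation`.
#' @param seq Residue string matching the annotation length.
#' @export
write_annotation_tsv <- function(annotation, seq, path) {
  r <- seq_residues(seq)
  stopifnot(length(r) == annotation$length)
  df <- data.frame(sequence_id = annotation$sequence_id,
                   position = seq_len(annotation$length),
                   residue = r,
                   helical = as.integer(annotation$helical),
                   in_membrane = as.integer(annotation$in_membrane))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kink-position list (TSV: sequence_id, position)
#'
#' @param path TSV file path.
#' @return Named list of integer vectors, one per sequence id.
#' @export
read_kinks_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence_id", "position") %in% names(df))) {
    stop(sprintf("kink TSV %s needs columns sequence_id, position", path),
         call. = FALSE)
  }
  lapply(split(as.integer(df$position), df$sequence_id), sort)
}

#' Write a result table as TSV or JSON
#'
#' Numeric columns are formatted to 4 decimal places in TSV output so that
#' identical inputs give byte-identical files.
#'
#' @param x Data frame.
#' @param path Output path (`"-"` for stdout).
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(x, path = "-", format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x))
  con <- if (identical(path, "-")) stdout() else file(path, "w")
  if (!identical(path, "-")) on.exit(close(con))
  if (format == "tsv") {
    y <- x
    for (j in seq_along(y)) {
      if (is.double(y[[j]])) y[[j]] <- sprintf("%.4f", y[[j]])
    }
    utils::write.table(y, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(jsonlite::toJSON(x, dataframe = "rows", digits = NA,
                                pretty = TRUE, na = "null"), con)
  }
  invisible(path)
}
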