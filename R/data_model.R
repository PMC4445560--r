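#' @title Sequence and metadata input handling
#' @name data_model
#' @description Read, validate, window and group aligned mtDNA control-region
#'   sequences anchored to the bovine reference V00654, and convert calendar
#'   ages (years BCE) to coalescent time (generations before present).
NULL

.SEQ_ALPHABET <- c("A", "C", "G", "T", "N", "-", "?")
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U", "X")

#' Construct a sequence record
#'
#' @param id sequence identifier.
#' @param seq character string over `A,C,G,T,N,-,?`.
#' @param anchor_start 1-based inclusive start position of the sequence on
#'   the V00654 reference.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, seq, anchor_start = 15914L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence for id '", id, "'")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), .SEQ_ALPHABET)
  if (length(bad)) {
    amb <- intersect(bad, .IUPAC_AMBIG)
    if (length(amb)) {
      warning("sequence '", id, "': ambiguity codes ",
              paste(amb, collapse = ","), " mapped to N")
      chars[chars %in% amb] <- "N"
      seq <- paste(chars, collapse = "")
      bad <- setdiff(bad, amb)
    }
    if (length(bad))
      stop("sequence '", id, "': invalid characters ", paste(bad, collapse = ","))
  }
  if (anchor_start < 1) stop("anchor_start must be >= 1")
  structure(list(id = id, seq = seq, anchor_start = as.integer(anchor_start)),
            class = "seq_record")
}

#' Read aligned sequences from a FASTA file
#'
#' Parsing is delegated to \pkg{seqinr}; a light pre-validation pass reports
#' malformed lines by number and rejects duplicate identifiers. Sequences are
#' uppercased; IUPAC ambiguity codes other than N are normalised to N with a
#' warning (downstream statistics only distinguish match / mismatch /
#' missing).
#'
#' @param path FASTA file path.
#' @param anchor_start default V00654 anchor for records whose header does
#'   not carry an `anchor=<pos>` token.
#' @return List of [seq_record()] objects.
#' @export
read_fasta <- function(path, anchor_start = 15914L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("malformed FASTA (", path, "): file is empty")
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA (", path, "): line ", nonblank[1],
         " does not start a '>' header")
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           whole.header = TRUE)
  heads <- vapply(fa, function(x) attr(x, "Annot"), character(1))
  heads <- sub("^>", "", heads)
  ids <- vapply(strsplit(heads, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  anchors <- rep(as.integer(anchor_start), length(ids))
  tok <- regmatches(heads, regexpr("anchor=[0-9]+", heads))
  has <- grepl("anchor=[0-9]+", heads)
  anchors[has] <- as.integer(sub("anchor=", "", tok))
  mapply(function(id, s, a) seq_record(id, as.character(s), a),
         ids, fa, anchors, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records list of [seq_record()].
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(sprintf(">%s anchor=%d", r$id, r$anchor_start), con)
    s <- r$seq
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct an aligned, windowed set of sequences
#'
#' @param seqs named character vector (names = sample ids), all the same
#'   length.
#' @param window integer pair: 1-based inclusive V00654 interval.
#' @return An `aligned_seqs` object.
#' @export
aligned_seqs <- function(seqs, window) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences have unequal lengths")
  window <- as.integer(window)
  if (len != window[2] - window[1] + 1L)
    stop("sequence length ", len, " does not match window span ",
         window[2] - window[1] + 1L)
  structure(list(seqs = seqs, window = window), class = "aligned_seqs")
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat(sprintf("aligned_seqs: %d sequences, window %d-%d (%d bp)\n",
              length(x$seqs), x$window[1], x$window[2],
              x$window[2] - x$window[1] + 1L))
  invisible(x)
}

#' @export
length.aligned_seqs <- function(x) length(x$seqs)

#' Extract a reference window from anchored records
#'
#' Coordinates are 1-based inclusive on V00654, e.g. the 399 bp ancient-DNA
#' window is (15914, 16312) and the 240 bp window shared with modern data is
#' (16023, 16262).
#'
#' @param records list of [seq_record()].
#' @param start,end window bounds on the reference.
#' @return [aligned_seqs()] of length `end - start + 1` per sequence.
#' @export
extract_window <- function(records, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (end < start) stop("end < start")
  spans <- vapply(records, function(r)
    r$anchor_start + nchar(r$seq) - 1L, integer(1))
  anchors <- vapply(records, function(r) r$anchor_start, integer(1))
  ids <- vapply(records, function(r) r$id, character(1))
  bad <- ids[anchors > start | spans < end]
  if (length(bad))
    stop("records not covering window [", start, ",", end, "]: ",
         paste(bad, collapse = ", "))
  seqs <- vapply(records, function(r) {
    off <- start - r$anchor_start
    substr(r$seq, off + 1L, off + (end - start + 1L))
  }, character(1))
  names(seqs) <- ids
  aligned_seqs(seqs, c(start, end))
}

#' Convert an age in years BCE to generations before present
#'
#' The present epoch is fixed at 2000 CE so that the model's two calendar
#' anchors land on round generation counts at 6 years/generation
#' (8,500 BCE = 1,750 generations BP; 6,400 BCE = 1,400 generations BP).
#'
#' @param age_bce age in years BCE (negative values are CE dates).
#' @param generation_time years per generation.
#' @param present_ce calendar year taken as the present.
#' @return Generations before present (real-valued).
#' @export
bce_to_generations <- function(age_bce, generation_time = 6, present_ce = 2000) {
  if (generation_time <= 0) stop("generation_time must be > 0")
  (age_bce + present_ce) / generation_time
}

.META_COLS <- c("sample_id", "site", "lat", "lon", "region_group",
                "age_bce_lo", "age_bce_hi", "epoch")

#' Default mapping from region group labels to demes
#'
#' Maps the thirteen ancient spatiotemporal groups (Iran/Syria, Western
#' Anatolia, Southeastern Europe, Southeastern Central Europe, Italy,
#' Southern France, Spain, Central/Western Europe, by period) and the two
#' synthetic modern groups to the NE (Near East/Anatolia) or EU (Europe)
#' deme. Used to derive the four ABC sample groups from `region_group` and
#' `epoch`.
#'
#' @return Named character vector, values in `c("NE", "EU")`.
#' @export
default_group_mapping <- function() {
  c("IR" = "NE", "IR/S" = "NE", "WA" = "NE",
    "SEE" = "EU", "SECE" = "EU", "IT" = "EU", "SF" = "EU", "SP" = "EU",
    "CWE" = "EU",
    "Near East (modern)" = "NE", "Europe (modern)" = "EU")
}

.region_to_deme <- function(region_group, mapping) {
  hit <- mapping[region_group]
  miss <- is.na(hit)
  if (any(miss)) {
    # fall back to the label's leading token (e.g. "IR 7,000-5,000 BCE")
    tok <- vapply(strsplit(region_group[miss], " ", fixed = TRUE),
                  `[`, character(1), 1L)
    hit[miss] <- mapping[tok]
  }
  if (anyNA(hit))
    stop("unknown region_group label(s): ",
         paste(unique(region_group[is.na(hit)]), collapse = ", "))
  unname(hit)
}

#' Read and validate the sample metadata table
#'
#' @param path TSV with columns `sample_id, site, lat, lon, region_group,
#'   age_bce_lo, age_bce_hi, epoch` (`age_bce_lo` is the older bound).
#' @param mapping region-group-to-deme mapping, see
#'   [default_group_mapping()].
#' @return data.frame with a derived `abc_group` column in
#'   `ancient_NE, ancient_EU, modern_NE, modern_EU`.
#' @export
read_metadata <- function(path, mapping = default_group_mapping()) {
  md <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  validate_metadata(md, mapping)
}

#' Validate a metadata data.frame and derive ABC groups
#'
#' @param md data.frame with the columns listed in [read_metadata()].
#' @param mapping see [default_group_mapping()].
#' @return The validated data.frame with `abc_group` added.
#' @export
validate_metadata <- function(md, mapping = default_group_mapping()) {
  miss <- setdiff(.META_COLS, names(md))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id(s) in metadata")
  if (anyNA(md$lat) || anyNA(md$lon))
    stop("metadata: missing lat/lon values")
  if (any(abs(md$lat) > 90) || any(abs(md$lon) > 180))
    stop("metadata: lat/lon out of range")
  if (!all(md$epoch %in% c("ancient", "modern")))
    stop("metadata: epoch must be 'ancient' or 'modern'")
  anc <- md$epoch == "ancient"
  if (any(anc & (is.na(md$age_bce_lo) | is.na(md$age_bce_hi))))
    stop("metadata: ancient samples need age_bce_lo and age_bce_hi")
  bad <- anc & !is.na(md$age_bce_lo) & !is.na(md$age_bce_hi) &
    md$age_bce_lo < md$age_bce_hi
  if (any(bad))
    stop("metadata: age_bce_lo < age_bce_hi (lo must be the older bound) for: ",
         paste(md$sample_id[bad], collapse = ", "))
  deme <- .region_to_deme(md$region_group, mapping)
  md$abc_group <- paste0(ifelse(md$epoch == "ancient", "ancient_", "modern_"),
                         deme)
  md
}

#' Point age (years BCE) per sample
#'
#' Ancient samples: midpoint of the metadata age range. Modern samples: the
#' present (0 generations BP).
#'
#' @param md validated metadata.
#' @param rule `"midpoint"` (per-sample midpoint, default) or
#'   `"group_midpoint"` (midpoint of the sample's region group pooled range).
#' @return Numeric vector of ages in years BCE (modern samples get
#'   `-present_ce` so that [bce_to_generations()] maps them to 0).
#' @export
sample_ages_bce <- function(md, rule = c("midpoint", "group_midpoint")) {
  rule <- match.arg(rule)
  age <- rep(NA_real_, nrow(md))
  anc <- md$epoch == "ancient"
  if (rule == "midpoint") {
    age[anc] <- (md$age_bce_lo[anc] + md$age_bce_hi[anc]) / 2
  } else {
    for (g in unique(md$region_group[anc])) {
      i <- anc & md$region_group == g
      age[i] <- (max(md$age_bce_lo[i]) + min(md$age_bce_hi[i])) / 2
    }
  }
  age[!anc] <- -2000
  age
}

#' Group an alignment by a metadata column
#'
#' @param aln [aligned_seqs()].
#' @param md validated metadata covering every sequence id.
#' @param by metadata column to split on (default `abc_group`).
#' @return Named list of `aligned_seqs`, one per group level.
#' @export
split_groups <- function(aln, md, by = "abc_group") {
  ids <- names(aln$seqs)
  miss <- setdiff(ids, md$sample_id)
  if (length(miss))
    stop("sequences without metadata: ", paste(head(miss, 5), collapse = ", "))
  key <- md[[by]][match(ids, md$sample_id)]
  lapply(split(seq_along(ids), key), function(i)
    aligned_seqs(aln$seqs[i], aln$window))
}
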