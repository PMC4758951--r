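## Readers and writers: probe TSV, model text format, MEME export, FASTA
## promoters, gene -> GO mapping, BED-like affinity scans, YAML config.

.MODEL_FORMAT_VERSION <- 1L

.outputHeader <- function(configLines = character(0)) {
  ver <- as.character(utils::packageVersion("psamfit"))
  hash <- .strHash(paste(configLines, collapse = "\n"))
  sprintf("# psamfit %s config=%s", ver, hash)
}

#' Read a probe table from TSV
#'
#' Expects a header line `probe_id<TAB>sequence<TAB>intensity`. Comment
#' lines starting with `#` are skipped; CRLF line endings are normalised;
#' sequences are uppercased. Ragged rows, duplicate probe identifiers,
#' non-ACGT sequences and non-numeric intensities are rejected with the
#' offending line number.
#'
#' @param path Path to the TSV file.
#' @return A [ProbeTable-class].
#' @export
readProbeTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  lineNo <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineNo <- lineNo[keep]
  if (length(lines) < 2L) stop("probe table has no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:3], c("probe_id", "sequence", "intensity")))
    stop("expected header 'probe_id\tsequence\tintensity'")
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != 3L))
    stop("ragged row at line ", lineNo[-1][which(lens != 3L)[1]])
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  ids <- m[, 1]
  seqs <- toupper(m[, 2])
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("non-ACGT sequence at line ", lineNo[-1][which(bad)[1]])
  y <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(y))
    stop("non-numeric intensity at line ", lineNo[-1][which(is.na(y))[1]])
  dupl <- duplicated(ids)
  if (any(dupl))
    stop("duplicate probe_id at line ", lineNo[-1][which(dupl)[1]])
  ProbeTable(ids, seqs, y)
}

#' Write a probe table to TSV
#'
#' @param probes A [ProbeTable-class].
#' @param path Output path.
#' @param header Optional extra comment lines (without leading `#`).
#' @return Invisibly, the path.
#' @export
writeProbeTable <- function(probes, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.outputHeader(header), con)
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("probe_id\tsequence\tintensity", con)
  writeLines(sprintf("%s\t%s\t%.17g", probes@probeId, probes@sequence,
                     probes@intensity), con)
  invisible(path)
}

## ---------------------------------------------------------------------
## model serialization
## ---------------------------------------------------------------------

.num <- function(x) sprintf("%.17g", x)

#' Write a fitted model to a text file
#'
#' Serialises a [FitState-class] or [BindingModeSet-class] (a
#' [FitState-class] is written as a single-mode set, preserving its frozen
#' PSAM scale). Matrices are stored as relative affinities
#' `exp(-ddG/RT)` at full double precision, so a write/read round trip
#' reproduces every ddG/RT, gamma and rel_Ka value to better than 1e-12.
#'
#' @param x A [FitState-class] or [BindingModeSet-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeModel <- function(x, path) {
  betaPsam <- NA_real_
  if (is(x, "FitState")) {
    betaPsam <- x@betaPsam
    x <- asBindingModeSet(x)
  }
  stopifnot(is(x, "BindingModeSet"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# psamfit model file")
  w("format_version: %d", .MODEL_FORMAT_VERSION)
  w("n_modes: %d", length(x@modes))
  w("beta0: %s", .num(x@im@beta0))
  w("beta1: %s", .num(x@im@beta1))
  w("ddG_ns: %s", .num(x@im@ddGns))
  w("saturating: %s", x@im@saturating)
  w("conc: %s", .num(x@im@conc))
  w("beta_psam: %s", .num(betaPsam))
  for (m in seq_along(x@modes)) {
    mod <- x@modes[[m]]
    bias <- x@biases[[m]]
    L <- motifLength(mod)
    w(">mode %d", m)
    w("rel_Ka: %s", .num(x@relKa[m]))
    w("mode_pvalue: %s", .num(x@modePvalues[m]))
    w("reference_seq: %s", mod@referenceSeq)
    w("symmetric: %s", mod@symmetric)
    w("strand_policy: %s", mod@strandPolicy)
    w("motif_length: %d", L)
    w("mono:")
    w("%s", paste(.BASES, collapse = "\t"))
    A <- exp(-mod@monoDdG)
    for (j in seq_len(L)) w("%s", paste(.num(A[, j]), collapse = "\t"))
    if (ncol(mod@diDdG)) {
      w("di:")
      w("%s", paste(.DINUCS, collapse = "\t"))
      Dm <- exp(-mod@diDdG)
      for (j in seq_len(L - 1L))
        w("%s", paste(.num(Dm[, j]), collapse = "\t"))
    }
    w("gamma: %d %d %s", bias@probeLength, bias@motifLength,
      bias@strandPolicy)
    vt <- .viewTable(bias@probeLength, bias@motifLength, bias@strandPolicy)
    for (k in seq_len(nrow(vt)))
      w("%d\t%s\t%s", vt$offset[k], vt$strand[k], .num(bias@gamma[k]))
  }
  w("end_of_model")
  invisible(path)
}

#' Read a model file
#'
#' @param path Path written by [writeModel()].
#' @return A [BindingModeSet-class]; the frozen PSAM scale, if present, is
#'   attached as attribute `betaPsam`.
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  pos <- 1L
  nextLine <- function() {
    while (pos <= length(lines) &&
           (startsWith(lines[pos], "#") || !nzchar(lines[pos])))
      pos <<- pos + 1L
    if (pos > length(lines)) stop("truncated model file: ", path)
    out <- lines[pos]
    pos <<- pos + 1L
    out
  }
  expectKey <- function(key) {
    ln <- nextLine()
    if (!startsWith(ln, paste0(key, ":")))
      stop("malformed model file: expected '", key, ":', got '", ln, "'")
    trimws(sub(paste0("^", key, ":"), "", ln))
  }
  num <- function(x) if (x %in% c("NA", "NaN")) NA_real_ else as.numeric(x)
  ver <- as.integer(expectKey("format_version"))
  if (is.na(ver) || ver != .MODEL_FORMAT_VERSION)
    stop("unsupported model file version: ", ver)
  nModes <- as.integer(expectKey("n_modes"))
  beta0 <- as.numeric(expectKey("beta0"))
  beta1 <- as.numeric(expectKey("beta1"))
  ddGns <- as.numeric(expectKey("ddG_ns"))
  saturating <- as.logical(expectKey("saturating"))
  conc <- as.numeric(expectKey("conc"))
  betaPsam <- num(expectKey("beta_psam"))
  modes <- list()
  biases <- list()
  rel <- numeric(nModes)
  pv <- numeric(nModes)
  for (m in seq_len(nModes)) {
    hdr <- nextLine()
    if (!identical(hdr, sprintf(">mode %d", m)))
      stop("malformed model file: expected '>mode ", m, "'")
    rel[m] <- as.numeric(expectKey("rel_Ka"))
    pv[m] <- num(expectKey("mode_pvalue"))
    ref <- expectKey("reference_seq")
    sym <- as.logical(expectKey("symmetric"))
    pol <- expectKey("strand_policy")
    L <- as.integer(expectKey("motif_length"))
    if (!identical(nextLine(), "mono:"))
      stop("malformed model file: expected 'mono:'")
    if (!identical(nextLine(), paste(.BASES, collapse = "\t")))
      stop("malformed model file: bad mono header")
    A <- matrix(NA_real_, 4L, L)
    for (j in seq_len(L))
      A[, j] <- as.numeric(strsplit(nextLine(), "\t", fixed = TRUE)[[1]])
    if (anyNA(A)) stop("malformed mono matrix in model file")
    peek <- nextLine()
    Dm <- NULL
    if (identical(peek, "di:")) {
      if (!identical(nextLine(), paste(.DINUCS, collapse = "\t")))
        stop("malformed model file: bad di header")
      Dm <- matrix(NA_real_, 16L, L - 1L)
      for (j in seq_len(L - 1L))
        Dm[, j] <- as.numeric(strsplit(nextLine(), "\t", fixed = TRUE)[[1]])
      if (anyNA(Dm)) stop("malformed di matrix in model file")
      peek <- nextLine()
    }
    if (!startsWith(peek, "gamma:"))
      stop("malformed model file: expected 'gamma:'")
    gg <- strsplit(trimws(sub("^gamma:", "", peek)), " +")[[1]]
    probeLen <- as.integer(gg[1])
    gL <- as.integer(gg[2])
    gPol <- gg[3]
    nv <- .nViews(probeLen, gL, gPol)
    gamma <- numeric(nv)
    for (k in seq_len(nv)) {
      f <- strsplit(nextLine(), "\t", fixed = TRUE)[[1]]
      gamma[k] <- as.numeric(f[3])
    }
    modes[[m]] <- featureModel(ref, -log(A),
                               diDdG = if (is.null(Dm)) NULL else -log(Dm),
                               symmetric = sym, strandPolicy = pol)
    biases[[m]] <- positionalBias(gamma, probeLen, gL, gPol)
  }
  if (!identical(nextLine(), "end_of_model"))
    stop("truncated model file: missing end marker")
  out <- new("BindingModeSet", modes = modes, relKa = rel,
             modePvalues = pv,
             im = intensityModel(beta0, beta1, ddGns, saturating, conc),
             biases = biases, details = list(source = path))
  attr(out, "betaPsam") <- betaPsam
  out
}

#' Export a PSAM as a minimal MEME motif
#'
#' Converts each PSAM column of relative affinities to probabilities by
#' per-position normalisation and writes minimal MEME motif format for
#' interoperability with motif tooling.
#'
#' @param model A [FeatureModel-class] (or [FitState-class]).
#' @param path Output path.
#' @param name Motif name (default: the reference sequence).
#' @return Invisibly, the path.
#' @export
exportMEME <- function(model, path, name = NULL) {
  if (is(model, "FitState")) model <- model@model
  stopifnot(is(model, "FeatureModel"))
  if (is.null(name)) name <- model@referenceSeq
  A <- exp(-model@monoDdG)
  Pm <- sweep(A, 2L, colSums(A), "/")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf(
                 "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                 ncol(Pm))), con)
  for (j in seq_len(ncol(Pm)))
    writeLines(paste(sprintf("%.6f", Pm[, j]), collapse = " "), con)
  invisible(path)
}

## ---------------------------------------------------------------------
## promoters, annotation, scans
## ---------------------------------------------------------------------

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file; the gene identifier is the first whitespace
#'   token of each record header.
#' @return Named character vector of uppercase sequences.
#' @export
readPromoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFastaSeqs <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a two-column gene-to-category mapping
#'
#' @param path TSV with two columns: gene id, category (no header, or a
#'   header line `gene_id<TAB>category`).
#' @return data.frame with columns `gene_id`, `category`.
#' @export
readGOMapping <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("annotation rows must have two tab-separated columns")
  m <- do.call(rbind, lapply(parts, `[`, 1:2))
  df <- data.frame(gene_id = m[, 1], category = m[, 2],
                   stringsAsFactors = FALSE)
  if (identical(tolower(df$gene_id[1]), "gene_id")) df <- df[-1, ]
  df
}

#' Per-window affinity scan (BED-like)
#'
#' Scores every view of every sequence under the model and returns a
#' BED-like table (0-based half-open coordinates).
#'
#' @param modeset A [BindingModeSet-class] or [FitState-class].
#' @param seqs Named character vector of sequences.
#' @param minAffinity Report only windows with `relKa * affinity` at or
#'   above this threshold (default 0, i.e. everything).
#' @return data.frame with columns `seqname`, `start`, `end`, `strand`,
#'   `mode`, `affinity`.
#' @export
scanAffinity <- function(modeset, seqs, minAffinity = 0) {
  modeset <- .toModeSet(modeset)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  rows <- list()
  for (sn in names(seqs)) {
    S <- .encodeSeqs(seqs[[sn]])
    for (m in seq_along(modeset@modes)) {
      mod <- modeset@modes[[m]]
      L <- motifLength(mod)
      if (L > ncol(S)) next
      aff <- modeset@relKa[m] * drop(.viewAffinityMatrix(S, mod))
      vt <- .viewTable(ncol(S), L, mod@strandPolicy)
      keep <- aff >= minAffinity
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        seqname = sn, start = vt$offset[keep],
        end = vt$offset[keep] + L, strand = vt$strand[keep], mode = m,
        affinity = aff[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(seqname = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mode = integer(0), affinity = numeric(0)))
  do.call(rbind, rows)
}

## ---------------------------------------------------------------------
## config files
## ---------------------------------------------------------------------

#' Read a YAML-style key/value config into a FitConfig
#'
#' Keys must match [fitConfig()] argument names; unknown keys are an
#' error. Values from `overrides` (e.g. parsed command-line flags) take
#' precedence.
#'
#' @param path Path to a YAML file, or NULL for defaults.
#' @param overrides Named list of overriding values.
#' @return A [FitConfig-class].
#' @export
readFitConfig <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("config file must be a key/value mapping")
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(fitConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(fitConfig, vals)
}

## fully-resolved config as key/value text lines (for run logs)
.configLines <- function(config) {
  sl <- slotNames(config)
  vapply(sl, function(s)
    sprintf("%s: %s", s, paste(format(slot(config, s)), collapse = ",")),
    "")
}
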