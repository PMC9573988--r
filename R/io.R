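# 17 significant digits: round-trips doubles exactly, keeping file
# checksums deterministic across runs.
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write genotypes as a minimal VCFv4.2 file
#'
#' Emits biallelic SNV records with hard-call GT fields (0/0, 0/1, 1/1;
#' "./." for missing) and the imputation-quality score, when present, as the
#' INFO key R2. Dosages are rounded to hard calls on output.
#'
#' @param g A [GenotypeMatrix-class].
#' @param path output file path (plain text).
#' @return invisibly, the path.
#' @export
writeGenotypesVCF <- function(g, path) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- hardCalls(dosages(g))
  info <- snvInfo(g)
  gtMap <- c("0/0", "0/1", "1/1")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t"))
  body <- vapply(seq_len(ncol(d)), function(j) {
    gt <- ifelse(is.na(d[, j]), "./.", gtMap[d[, j] + 1L])
    infoField <- if (is.na(info$quality[j])) "." else
      paste0("R2=", .fmtNum(info$quality[j]))
    paste(c(info$chrom[j], info$pos[j], info$snv[j], info$ref[j],
            info$alt[j], ".", "PASS", infoField, "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCFv4.2 file into a [GenotypeMatrix-class]. Dosage is the count
#' of alternate alleles from GT ("./." = missing); when GT is absent the DS
#' FORMAT field is used instead. Multiallelic records are skipped with a
#' warning. Imputation quality is read from the INFO key R2 when present.
#'
#' @param path VCF file path.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypesVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning("readGenotypesVCF: skipping ", sum(multi),
            " multiallelic record(s)")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  fmt <- unique(unlist(strsplit(v@gt[, 1], ":", fixed = TRUE)))
  if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("|", "/", gt, fixed = TRUE)
    dose[] <- vapply(clean, function(x) {
      if (is.na(x) || x %in% c("./.", ".")) return(NA_real_)
      sum(as.integer(strsplit(x, "/", fixed = TRUE)[[1]]) > 0)
    }, numeric(1))
  } else if ("DS" %in% fmt) {
    dose <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    stop("readGenotypesVCF: neither GT nor DS found in FORMAT")
  }
  r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, "R2")))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  info <- data.frame(snv = ids, chrom = fix$CHROM,
                     pos = as.numeric(fix$POS), ref = fix$REF,
                     alt = fix$ALT, gene = NA_character_,
                     quality = r2, stringsAsFactors = FALSE)
  d <- t(dose)
  colnames(d) <- ids
  genotypeMatrix(d, info)
}

#' Write a metabolite matrix as CSV
#'
#' RFC-4180 CSV with a header row; first column \code{sample_id}, one
#' column per metabolite, missing encoded as empty cells. Analyte classes
#' are written alongside as \code{<path>.classes.csv}.
#'
#' @param m A [MetaboliteMatrix-class].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeMetabolitesCSV <- function(m, path) {
  stopifnot(is(m, "MetaboliteMatrix"))
  a <- abundances(m)
  df <- data.frame(sample_id = rownames(a), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(a))) df[[colnames(a)[j]]] <- .fmtNum(a[, j])
  df[df == "NA"] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(metabolite = colnames(a),
                              class = analyteClass(m),
                              stringsAsFactors = FALSE),
                   paste0(path, ".classes.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a metabolite matrix from CSV
#'
#' @param path CSV with header; first column sample ids, remaining columns
#'   metabolite abundances; missing as empty cells or "NA".
#' @param classPath optional CSV (metabolite, class) of analyte classes;
#'   defaults to \code{<path>.classes.csv} when that file exists.
#' @return A [MetaboliteMatrix-class].
#' @export
readMetabolitesCSV <- function(path, classPath = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  a <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(a) <- "double"
  rownames(a) <- as.character(df[[1]])
  if (is.null(classPath)) {
    cand <- paste0(path, ".classes.csv")
    if (file.exists(cand)) classPath <- cand
  }
  cls <- NULL
  if (!is.null(classPath)) {
    cdf <- utils::read.csv(classPath, stringsAsFactors = FALSE)
    cls <- cdf$class[match(colnames(a), cdf$metabolite)]
    cls[is.na(cls)] <- "other"
  }
  metaboliteMatrix(a, cls)
}

#' Write a phenotype table as CSV
#'
#' @param pheno data.frame (see [validatePhenotypes()]).
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writePhenotypesCSV <- function(pheno, path) {
  out <- pheno
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .fmtNum(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' @param path CSV with header; needs at least sample_id and attempt.
#' @return validated data.frame (see [validatePhenotypes()]).
#' @export
readPhenotypesCSV <- function(path) {
  validatePhenotypes(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a simulated cohort to disk
#'
#' Writes the genotypes as VCFv4.2, metabolites and phenotypes as CSV, the
#' ground truth as JSON, and a run-metadata JSON recording paths and the
#' seed.
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    metabolites = file.path(dir, "metabolites.csv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    truth = file.path(dir, "truth.json"),
    metadata = file.path(dir, "run_metadata.json"))
  writeGenotypesVCF(cohort$genotypes, paths$vcf)
  writeMetabolitesCSV(cohort$metabolites, paths$metabolites)
  writePhenotypesCSV(cohort$phenotypes, paths$phenotypes)
  tr <- cohort$truth
  jsonlite::write_json(
    list(effects = tr@effects, maf = tr@maf,
         responseLinks = tr@responseLinks, seed = tr@seed),
    paths$truth, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(paths = paths[c("vcf", "metabolites", "phenotypes", "truth")],
         seed = tr@seed, created = "simulated cohort"),
    paths$metadata, auto_unbox = TRUE)
  invisible(paths)
}

#' Simulate a cohort and write it to disk
#'
#' Thin wrapper over [generateCohort()] + [writeCohort()].
#'
#' @param config A [SimConfig-class]; its seed is overridden by \code{seed}
#'   when given.
#' @param dir output directory.
#' @param seed optional integer seed override.
#' @return invisibly, the written paths.
#' @export
simulateToFiles <- function(config = simConfig(), dir, seed = NULL) {
  if (!is.null(seed)) config@seed <- as.integer(seed)
  writeCohort(generateCohort(config), dir)
}

#' Write a network as GraphML
#'
#' Node attributes: block, community, centrality; edge attributes: weight
#' (absolute), signedWeight, p.
#'
#' @param net An [OmicsNetwork-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNetworkGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' Write a network edge list as TSV
#'
#' @param net An [OmicsNetwork-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEdgeListTSV <- function(net, path) {
  e <- netEdges(net)
  out <- data.frame(from = e$from, to = e$to,
                    weight = .fmtNum(e$weight), p = .fmtNum(e$p),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' Overlays values from a YAML file on [runConfig()] defaults. Top-level
#' keys mirror the runConfig arguments; a \code{network} section holds
#' r_threshold, alpha, components, keepX, seed.
#'
#' @param path YAML file.
#' @return a run-configuration list (see [runConfig()]).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  nw <- y$network
  net <- networkConfig(
    rThreshold = nw$r_threshold %||% 0.1,
    alpha = nw$alpha %||% 0.05,
    ncomp = nw$components %||% 3L,
    keepX = nw$keepX,
    seed = nw$seed %||% (y$seed %||% 1L))
  runConfig(
    vcf = y$vcf, metabolites = y$metabolites, phenotypes = y$phenotypes,
    outDir = y$out_dir %||% ".",
    maxMissingFrac = y$missingness %||% 0.10,
    minCallRate = y$call_rate %||% 0.95,
    minQuality = y$quality %||% 0.95,
    minMAF = y$maf %||% 0.05,
    alpha = y$alpha %||% 0.05,
    ldR2 = y$ld_r2 %||% 0.8,
    knnK = y$knn_k %||% 5L,
    network = net,
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
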