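#' Construct a genotype matrix object
#'
#' Couples an individuals-by-markers allele-dosage matrix (codes 0/1/2, `NA`
#' for missing) with its marker map.  Markers are stored sorted by
#' (chromosome, position); positions are 1-based base pairs.
#'
#' @param geno integer matrix, rows = individuals (rownames are ids),
#'   columns = markers (colnames are marker ids); entries 0/1/2/`NA`.
#' @param map data.frame with columns `marker`, `chrom`, `pos`.
#' @return object of class `genotypes` with elements `geno` and `map`.
#' @export
genotypes <- function(geno, map) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)), !is.null(colnames(geno)))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (anyDuplicated(map$marker))
    stop("duplicate marker id(s): ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  if (!identical(sort(colnames(geno)), sort(map$marker)))
    stop("geno columns and map markers do not agree")
  ord <- order(chrom_order(map$chrom), map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  geno <- geno[, map$marker, drop = FALSE]
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  structure(list(geno = geno, map = map), class = "genotypes")
}

# Numeric-first chromosome ordering; non-numeric labels (e.g. "Z") follow.
chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(num), Inf, num)
  # stable secondary order for non-numeric labels
  key + match(chrom, sort(unique(chrom))) * 1e-9
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.4g%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$geno)

#' Is a marker on the Z (sex) chromosome?
#'
#' Z-linked markers are retained on input but excluded from crossover
#' detection; they remain available to the whole-genome regression.
#'
#' @param map marker map data.frame.
#' @return logical vector along the map rows.
#' @export
is_z_marker <- function(map) toupper(map$chrom) == "Z"

#' Read genotypes from disk
#'
#' Two dialects are supported: PLINK-style `ped/map` (whitespace-separated,
#' two allele columns per marker coded 1/2, "0 0" missing; dosage is the
#' count of allele 2) and `matrix` (a TSV with individual ids in the first
#' column and one 0/1/2/NA dosage column per marker, plus a 3-column TSV map
#' `marker chrom pos`).
#'
#' @param path for `dialect = "ped"`, path to the `.ped` file; for
#'   `dialect = "matrix"`, path to the dosage TSV.
#' @param map_path path to the `.map` (PLINK: chrom, marker, cM, pos) or the
#'   map TSV (`marker chrom pos`, with header).
#' @param dialect `"ped"` or `"matrix"`.
#' @return [genotypes] object with markers sorted by (chromosome, position).
#' @export
read_genotypes <- function(path, map_path, dialect = c("ped", "matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(map_path)) stop("file not found: ", map_path)
  if (dialect == "ped") {
    mp <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(mp) < 4) stop("malformed map: expected 4 columns (chrom, marker, cM, pos)")
    map <- data.frame(marker = as.character(mp[[2]]), chrom = as.character(mp[[1]]),
                      pos = as.numeric(mp[[4]]), stringsAsFactors = FALSE)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    m <- nrow(map)
    geno <- matrix(NA_integer_, length(lines), m)
    ids <- character(length(lines))
    for (i in seq_along(lines)) {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(f) != 6 + 2 * m)
        stop(sprintf("malformed ped line %d: %d fields, expected %d",
                     i, length(f), 6 + 2 * m))
      ids[i] <- f[2]
      a1 <- f[seq(7, by = 2, length.out = m)]
      a2 <- f[seq(8, by = 2, length.out = m)]
      d <- (a1 == "2") + (a2 == "2")
      d[a1 == "0" | a2 == "0"] <- NA_integer_
      geno[i, ] <- as.integer(d)
    }
    rownames(geno) <- ids
    colnames(geno) <- map$marker
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    geno <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(geno) <- "integer"
    rownames(geno) <- ids
    map <- read.table(map_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    names(map)[1:3] <- c("marker", "chrom", "pos")
  }
  genotypes(geno, map)
}

#' Write genotypes in ped/map or matrix dialect
#'
#' @param G [genotypes] object.
#' @param path,map_path output paths (see [read_genotypes()] for formats).
#' @param ped optional pedigree data.frame supplying family/sire/dam/sex
#'   columns for the `.ped` dialect; unknown fields are written as 0.
#' @param dialect `"ped"` or `"matrix"`.
#' @return invisibly, `path`.
#' @export
write_genotypes <- function(G, path, map_path, ped = NULL,
                            dialect = c("ped", "matrix")) {
  dialect <- match.arg(dialect)
  if (dialect == "ped") {
    map <- G$map
    write.table(data.frame(map$chrom, map$marker, 0, format(map$pos, scientific = FALSE, trim = TRUE)),
                map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
    ids <- rownames(G$geno)
    sire <- dam <- rep("0", length(ids)); sex <- rep("0", length(ids))
    if (!is.null(ped)) {
      ix <- match(ids, ped$id)
      sire <- ifelse(is.na(ix) | is.na(ped$sire[ix]), "0", ped$sire[ix])
      dam <- ifelse(is.na(ix) | is.na(ped$dam[ix]), "0", ped$dam[ix])
      sex <- ifelse(is.na(ix), "0", ifelse(ped$sex[ix] == "M", "1", "2"))
    }
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_along(ids)) {
      d <- G$geno[i, ]
      a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, "2", "1"))
      a2 <- ifelse(is.na(d), "0", ifelse(d == 2, "2", "1"))
      al <- as.vector(rbind(a1, a2))
      writeLines(paste(c("FAM", ids[i], sire[i], dam[i], sex[i], "-9", al),
                       collapse = " "), con)
    }
  } else {
    tab <- data.frame(id = rownames(G$geno), G$geno, check.names = FALSE)
    write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
    write.table(G$map[, c("marker", "chrom", "pos")], map_path, quote = FALSE,
                row.names = FALSE, sep = "\t")
  }
  invisible(path)
}

#' Read a pedigree file
#'
#' Whitespace- or tab-separated table with columns id, sire, dam, sex
#' (header optional; sex coded M/F or 1/2; unknown parents as 0, NA or "-").
#' Records are returned in topological order (parents before offspring).
#'
#' @param path file path.
#' @return data.frame `id`, `sire`, `dam`, `sex` with `NA` for unknown
#'   parents, class `c("pedigree","data.frame")`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("id", tolower(first))
  tab <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("pedigree needs 4 columns: id, sire, dam, sex")
  names(tab)[1:4] <- c("id", "sire", "dam", "sex")
  as_pedigree(tab)
}

#' Coerce a data.frame to a topologically ordered pedigree
#'
#' @param tab data.frame with columns id, sire, dam, sex.
#' @return pedigree data.frame in topological order.
#' @export
as_pedigree <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  tab$id <- as.character(tab$id)
  unk <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "-", "NA")] <- NA
    x
  }
  tab$sire <- unk(tab$sire); tab$dam <- unk(tab$dam)
  sx <- toupper(as.character(tab$sex))
  sx[sx %in% c("1", "M", "MALE")] <- "M"
  sx[sx %in% c("2", "F", "FEMALE")] <- "F"
  if (!all(sx %in% c("M", "F")))
    stop("unknown sex code(s): ", paste(unique(sx[!sx %in% c("M", "F")]), collapse = ", "))
  tab$sex <- sx
  if (anyDuplicated(tab$id)) stop("duplicate individual ids in pedigree")
  # Kahn toposort; parents referenced but absent are treated as founders.
  ids <- tab$id
  done <- character(0)
  pending <- tab
  ordered <- tab[0, ]
  repeat {
    ready <- with(pending,
                  (is.na(sire) | sire %in% done | !(sire %in% ids)) &
                  (is.na(dam) | dam %in% done | !(dam %in% ids)))
    if (!any(ready)) break
    ordered <- rbind(ordered, pending[ready, , drop = FALSE])
    done <- c(done, pending$id[ready])
    pending <- pending[!ready, , drop = FALSE]
    if (nrow(pending) == 0) break
  }
  if (nrow(pending) > 0)
    stop("pedigree cycle involving: ", paste(pending$id, collapse = ", "))
  rownames(ordered) <- NULL
  class(ordered) <- c("pedigree", "data.frame")
  ordered
}

#' Write a pedigree TSV
#' @param ped pedigree data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped[, c("id", "sire", "dam", "sex")]
  out$sire[is.na(out$sire)] <- "0"; out$dam[is.na(out$dam)] <- "0"
  write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
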