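#' Read a PoPoolation2-style synchronized allele-count file
#'
#' Each line is `chrom<TAB>pos<TAB>ref` followed by one `A:T:C:G:N:del` read
#' count field per pool. Positions are 1-based (mpileup convention). Sync
#' files carry no pool names, so the column order must match the metadata row
#' order; only the column count is validated here.
#'
#' @param path sync file path
#' @param poolMeta data.frame with `name`, `n_individuals`, `latitude`,
#'   `longitude`; one row per sync count column, in file column order.
#' @return a [PoolCounts-class]
#' @export
readSync <- function(path, poolMeta) {
  nPools <- nrow(poolMeta)
  dt <- if (file.size(path) == 0L) data.table::data.table()
  else data.table::fread(path, sep = "\t", header = FALSE,
                         colClasses = "character", fill = TRUE)
  if (nrow(dt) == 0L) {
    empty <- matrix(integer(), 0, nPools)
    return(PoolCounts(stats::setNames(rep(list(empty), 6L), SYNC_BASES),
                      data.frame(chrom = character(), pos = integer(),
                                 ref = character()),
                      poolMeta))
  }
  if (ncol(dt) != 3L + nPools)
    stop(sprintf("sync file has %d columns; expected %d (3 + %d pools)",
                 ncol(dt), 3L + nPools, nPools))
  counts <- stats::setNames(
    rep(list(matrix(NA_integer_, nrow(dt), nPools)), 6L), SYNC_BASES)
  for (j in seq_len(nPools)) {
    field <- dt[[3L + j]]
    parts <- data.table::tstrsplit(field, ":", fixed = TRUE)
    if (length(parts) != 6L) {
      bad <- which(lengths(strsplit(field, ":", fixed = TRUE)) != 6L)[1]
      stop(sprintf("malformed count field '%s' at line %d (pool column %d)",
                   field[bad], bad, j))
    }
    for (b in seq_len(6L)) {
      v <- suppressWarnings(as.integer(parts[[b]]))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1]
        stop(sprintf("malformed count field '%s' at line %d (pool column %d)",
                     field[bad], bad, j))
      }
      counts[[b]][, j] <- v
    }
  }
  loci <- data.frame(chrom = dt[[1]], pos = as.integer(dt[[2]]),
                     ref = dt[[3]])
  PoolCounts(counts, loci, poolMeta)
}

#' Write a PoolCounts object as a sync file
#'
#' `readSync(writeSync(x))` round-trips bit-exactly on the integer counts.
#'
#' @param x a [PoolCounts-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSync <- function(x, path) {
  rr <- rowRanges(x)
  fields <- lapply(seq_len(ncol(x)), function(j) {
    paste(assay(x, "A")[, j], assay(x, "T")[, j], assay(x, "C")[, j],
          assay(x, "G")[, j], assay(x, "N")[, j], assay(x, "del")[, j],
          sep = ":")
  })
  dt <- data.table::as.data.table(
    c(list(chrom = as.character(seqnames(rr)), pos = start(rr),
           ref = rr$ref), fields))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read pool metadata and site environment tables
#'
#' Both files are delimited text with a header. The pool table needs columns
#' `name`, `n_individuals`, `latitude`, `longitude`; the environment table a
#' `site` column plus one numeric column per variable. Rows are aligned by
#' name and any mismatch is an error listing the offending names.
#'
#' @param poolPath path to the pool metadata CSV/TSV
#' @param envPath path to the site x environment CSV/TSV
#' @return list with elements `pools` (data.frame) and `env` (data.frame with
#'   sites as rows, in pool order)
#' @export
readStudyTables <- function(poolPath, envPath) {
  pools <- as.data.frame(data.table::fread(poolPath, header = TRUE))
  need <- c("name", "n_individuals", "latitude", "longitude")
  if (!all(need %in% names(pools)))
    stop("pool table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(pools$name))
    stop("duplicated pool names: ",
         paste(unique(pools$name[duplicated(pools$name)]), collapse = ", "))
  if (any(abs(pools$latitude) > 90) || any(abs(pools$longitude) > 180))
    stop("latitude/longitude out of bounds for pools: ",
         paste(pools$name[abs(pools$latitude) > 90 |
                          abs(pools$longitude) > 180], collapse = ", "))
  env <- as.data.frame(data.table::fread(envPath, header = TRUE))
  if (!"site" %in% names(env)) stop("environment table needs a 'site' column")
  orphan <- setdiff(env$site, pools$name)
  if (length(orphan))
    stop("environment sites with no matching pool: ",
         paste(orphan, collapse = ", "))
  missing <- setdiff(pools$name, env$site)
  if (length(missing))
    stop("pools with no environment row: ", paste(missing, collapse = ", "))
  env <- env[match(pools$name, env$site), , drop = FALSE]
  rownames(env) <- env$site
  list(pools = pools, env = env[, setdiff(names(env), "site"), drop = FALSE])
}
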