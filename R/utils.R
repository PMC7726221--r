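# internal helpers shared across modules

# polynomial rolling hash (mod 2^31 - 1) of the deparsed object;
# provenance stamp for output tables
.configHash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# union width (bp) of 1-based inclusive intervals on possibly many chromosomes
.intervalUnionWidth <- function(chrom, start, end) {
  if (length(start) == 0L) return(0)
  total <- 0
  for (ch in unique(chrom)) {
    i <- chrom == ch
    ir <- IRanges::reduce(IRanges::IRanges(start = start[i], end = end[i]))
    total <- total + sum(IRanges::width(ir))
  }
  total
}

.sampleVar <- function(x) stats::var(as.numeric(x))

# provenance header written above TSV tables
.writeTsv <- function(df, path, seed = NA, hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hapblup %s | seed=%s | config=%s",
                     as.character(utils::packageVersion("hapblup")),
                     as.character(seed), as.character(hash)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

.stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
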