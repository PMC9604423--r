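.CONTEXTS <- c("CG", "CHG", "CHH")

#' Build a cytosine-record GRanges
#'
#' Cytosine records are represented as a width-1 [GenomicRanges::GRanges]
#' with metadata columns `n_meth`, `n_unmeth`, `context` and `trinucleotide`.
#'
#' @param chrom chromosome identifiers.
#' @param pos 1-based positions.
#' @param strand `"+"` or `"-"`.
#' @param nMeth,nUnmeth non-negative read counts.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param trinucleotide 3-mers over A, C, G, T, N (strand-local, 5' to 3').
#' @return A `GRanges` of cytosine records.
#' @examples
#' cytosineRecords("chr1", 100, "+", 8, 2, "CHH", "CAT")
#' @export
cytosineRecords <- function(chrom, pos, strand, nMeth, nUnmeth, context,
                            trinucleotide) {
    nMeth <- as.integer(nMeth)
    nUnmeth <- as.integer(nUnmeth)
    if (any(nMeth < 0) || any(nUnmeth < 0))
        stop("read counts must be non-negative")
    bad <- !context %in% .CONTEXTS
    if (any(bad))
        stop("unknown context token(s): ",
             paste(unique(context[bad]), collapse = ", "))
    gr <- GRanges(chrom, IRanges(as.numeric(pos), width = 1L),
                  strand = strand)
    mcols(gr)$n_meth <- nMeth
    mcols(gr)$n_unmeth <- nUnmeth
    mcols(gr)$context <- as.character(context)
    mcols(gr)$trinucleotide <- as.character(trinucleotide)
    gr
}

#' Read a Bismark cytosine ("CX") report
#'
#' Parses the tab-delimited per-cytosine layout written by Bismark's
#' cytosine report: chromosome, 1-based position, strand, methylated read
#' count, unmethylated read count, context (CG/CHG/CHH), trinucleotide.
#'
#' @param path path to the report (no header).
#' @return Cytosine records as built by [cytosineRecords()]; an empty file
#'   yields an empty `GRanges`.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t100\t+\t8\t2\tCHH\tCAT", f)
#' readCytosineReport(f)
#' @export
readCytosineReport <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0L)
        return(cytosineRecords(character(), numeric(), character(),
                               integer(), integer(), character(),
                               character()))
    dt <- fread(path, header = FALSE, sep = "\t",
                colClasses = list(character = c(1, 3, 6, 7)))
    if (ncol(dt) != 7L)
        stop("expected 7 tab-delimited columns, found ", ncol(dt))
    names(dt) <- c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                   "context", "trinucleotide")
    badCtx <- which(!dt$context %in% .CONTEXTS)
    if (length(badCtx))
        stop("unknown context token at line(s) ",
             paste(head(badCtx, 5), collapse = ", "),
             ": ", paste(unique(dt$context[badCtx]), collapse = ", "))
    for (col in c("pos", "n_meth", "n_unmeth")) {
        v <- dt[[col]]
        if (!is.numeric(v) || anyNA(v) || any(v != floor(v)))
            stop("non-integer values in column '", col, "' at line(s) ",
                 paste(head(which(!is.finite(v) | v != floor(v)), 5),
                       collapse = ", "))
    }
    cytosineRecords(dt$chrom, dt$pos, dt$strand, dt$n_meth, dt$n_unmeth,
                    dt$context, dt$trinucleotide)
}

#' Write cytosine records in Bismark CX layout
#'
#' @param records cytosine records (see [cytosineRecords()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCytosineReport <- function(records, path) {
    dt <- data.table(
        chrom = as.character(seqnames(records)),
        pos = start(records),
        strand = as.character(strand(records)),
        n_meth = mcols(records)$n_meth,
        n_unmeth = mcols(records)$n_unmeth,
        context = mcols(records)$context,
        trinucleotide = mcols(records)$trinucleotide
    )
    fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Per-cytosine methylation level
#'
#' The fraction of reads calling a cytosine methylated,
#' n_meth / (n_meth + n_unmeth). Undefined (`NA`) at zero coverage --
#' never a division error.
#'
#' @param records cytosine records, or an integer vector of methylated
#'   counts when `nUnmeth` is given.
#' @param nUnmeth optional unmethylated counts (vector interface).
#' @return numeric vector of levels in [0, 1], `NA` where coverage is 0.
#' @examples
#' methylationLevel(3, 1)   # 0.75
#' methylationLevel(0, 0)   # NA
#' @export
methylationLevel <- function(records, nUnmeth = NULL) {
    if (is.null(nUnmeth)) {
        m <- mcols(records)$n_meth
        u <- mcols(records)$n_unmeth
    } else {
        m <- records
        u <- nUnmeth
    }
    cov <- m + u
    ifelse(cov > 0, m / cov, NA_real_)
}

#' Select highly methylated cytosines
#'
#' Keeps records whose methylation level is defined and strictly greater
#' than `levelThreshold` ("greater than 75%" read literally: a record at
#' exactly the threshold is excluded), with coverage at least `minCoverage`.
#' Order-preserving and idempotent.
#'
#' @param records cytosine records.
#' @param levelThreshold level cut-off in [0, 1]; default 0.75.
#' @param minCoverage minimum total read count; default 1.
#' @param verbose log per-context kept counts.
#' @return the kept subset of `records`.
#' @export
selectMethylated <- function(records, levelThreshold = 0.75,
                             minCoverage = 1L, verbose = FALSE) {
    stopifnot(levelThreshold >= 0, levelThreshold <= 1, minCoverage >= 1)
    lev <- methylationLevel(records)
    cov <- mcols(records)$n_meth + mcols(records)$n_unmeth
    keep <- !is.na(lev) & lev > levelThreshold & cov >= minCoverage
    kept <- records[keep]
    if (verbose) {
        tab <- table(factor(mcols(kept)$context, levels = .CONTEXTS))
        message("selectMethylated: kept ", length(kept), "/",
                length(records), " records (",
                paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                      collapse = ", "), ")")
    }
    kept
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.contextFromBases <- function(b1, b2) {
    h <- c("A", "C", "T")
    ctx <- rep(NA_character_, length(b1))
    ctx[b1 == "G"] <- "CG"
    ctx[b1 %in% h & b2 == "G"] <- "CHG"
    ctx[b1 %in% h & b2 %in% h] <- "CHH"
    ctx
}

#' Classify the sequence context of a cytosine
#'
#' Determines CG / CHG / CHH (H = A, C or T) from the two bases downstream
#' of the cytosine in the 5' to 3' direction of its strand. On the minus
#' strand, downstream means decreasing reference coordinate and the bases
#' are complemented. Returns `NA` where a needed base is N or off the
#' chromosome end.
#'
#' @param genome a [Biostrings::DNAStringSet] (or named character vector of
#'   sequences) keyed by chromosome.
#' @param chrom,pos,strand parallel vectors locating the cytosines
#'   (1-based positions).
#' @param check error if the reference base at a position is not a cytosine
#'   on the given strand (C on `+`, G on `-`); default TRUE.
#' @return character vector of contexts (`NA` where undefined).
#' @export
classifyContext <- function(genome, chrom, pos, strand, check = TRUE) {
    if (is(genome, "DNAStringSet"))
        genome <- setNames(as.character(genome), names(genome))
    n <- max(length(chrom), length(pos), length(strand))
    chrom <- rep_len(as.character(chrom), n)
    pos <- rep_len(as.numeric(pos), n)
    strand <- rep_len(as.character(strand), n)
    ctx <- rep(NA_character_, n)
    for (ch in unique(chrom)) {
        if (!ch %in% names(genome)) stop("chromosome not in genome: ", ch)
        s <- genome[[ch]]
        L <- nchar(s)
        i <- which(chrom == ch)
        p <- pos[i]
        if (any(p < 1 | p > L))
            stop("position outside chromosome ", ch)
        base <- substring(s, p, p)
        plus <- strand[i] == "+"
        if (check) {
            wrong <- (plus & base != "C") | (!plus & base != "G")
            if (any(wrong))
                stop("not a cytosine on the given strand at ", ch, ":",
                     p[wrong][1], " (", strand[i][wrong][1], ")")
        }
        b1 <- b2 <- rep(NA_character_, length(i))
        # plus strand: downstream bases at pos+1, pos+2
        ip <- which(plus)
        if (length(ip)) {
            ok1 <- ip[p[ip] + 1 <= L]
            ok2 <- ip[p[ip] + 2 <= L]
            if (length(ok1))
                b1[ok1] <- substring(s, p[ok1] + 1, p[ok1] + 1)
            if (length(ok2))
                b2[ok2] <- substring(s, p[ok2] + 2, p[ok2] + 2)
        }
        # minus strand: complements of pos-1, pos-2
        im <- which(!plus)
        if (length(im)) {
            ok1 <- im[p[im] - 1 >= 1]
            ok2 <- im[p[im] - 2 >= 1]
            if (length(ok1))
                b1[ok1] <- .complement[substring(s, p[ok1] - 1, p[ok1] - 1)]
            if (length(ok2))
                b2[ok2] <- .complement[substring(s, p[ok2] - 2, p[ok2] - 2)]
        }
        b1[b1 %in% "N"] <- NA
        b2[b2 %in% "N"] <- NA
        # a CG call needs only the first downstream base
        cc <- .contextFromBases(ifelse(is.na(b1), "N", b1),
                                ifelse(is.na(b2), "N", b2))
        cc[is.na(b1)] <- NA
        cc[!is.na(b1) & b1 != "G" & is.na(b2)] <- NA
        ctx[i] <- cc
    }
    ctx
}

#' Validate record contexts against a genome
#'
#' Re-derives every record's context from the genome with
#' [classifyContext()] and compares it with the record's context column.
#' Mismatching records are rejected with a warning reporting the count,
#' never silently corrected.
#'
#' @param records cytosine records.
#' @param genome genome sequences (see [classifyContext()]).
#' @return records whose context agrees with the genome; attribute
#'   `n_mismatch` carries the number rejected.
#' @export
validateContexts <- function(records, genome) {
    derived <- classifyContext(genome, as.character(seqnames(records)),
                               start(records), as.character(strand(records)))
    ok <- !is.na(derived) & derived == mcols(records)$context
    nbad <- sum(!ok)
    if (nbad > 0)
        warning(nbad, " record(s) rejected: context label disagrees ",
                "with the genome sequence")
    out <- records[ok]
    attr(out, "n_mismatch") <- nbad
    out
}
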