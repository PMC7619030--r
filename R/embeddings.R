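#' Read a fastText-style `.vec` embedding file
#'
#' Parses the plain-text `.vec` dialect: a header line `"<count> <dim>"`
#' followed by one `"<token> v1 ... vdim"` line per token, space-separated,
#' UTF-8. Lookups on the resulting store are byte-exact on the token: no case
#' folding, no unicode normalization, internal spaces are not special (the
#' token is everything before the last `dim` fields).
#'
#' @param path Path to a `.vec` file.
#' @return An `embedding_store`: a list with `dim` (vector dimensionality)
#'   and `entries` (a named list of numeric vectors, one per token).
#' @details Duplicate tokens collapse with a warning; the last occurrence
#'   wins. Any line whose numeric tail does not have exactly `dim` parseable
#'   components aborts with the offending line number.
#' @seealso [get_label_vector()], [write_vec_file()]
#' @export
read_vec_file <- function(path) {
  if (!file.exists(path)) {
    stop("embedding file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty .vec file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    stop(".vec header must be '<count> <dim>', got: ", lines[[1L]], call. = FALSE)
  }
  n_declared <- as.integer(header[[1L]])
  dim <- as.integer(header[[2L]])
  if (dim < 1L) stop(".vec header dimension must be positive", call. = FALSE)

  body <- lines[-1L]
  entries <- vector("list", length(body))
  labels <- character(length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(body[[i]], " ", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) != dim + 1L) {
      # multi-word token: the vector is the trailing dim fields
      if (length(fields) < dim + 1L) {
        stop(sprintf(".vec parse error at line %d: %d vector components, expected %d",
                     i + 1L, length(fields) - 1L, dim), call. = FALSE)
      }
      token <- paste(fields[seq_len(length(fields) - dim)], collapse = " ")
      vals <- fields[(length(fields) - dim + 1L):length(fields)]
    } else {
      token <- fields[[1L]]
      vals <- fields[-1L]
    }
    vec <- suppressWarnings(as.numeric(vals))
    if (anyNA(vec)) {
      stop(sprintf(".vec parse error at line %d: non-numeric vector component", i + 1L),
           call. = FALSE)
    }
    labels[[i]] <- token
    entries[[i]] <- vec
  }
  if (length(entries) != n_declared) {
    warning(sprintf(".vec header declares %d tokens, parsed %d", n_declared,
                    length(entries)), call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    dups <- unique(labels[duplicated(labels)])
    warning(sprintf("%d duplicate token(s) in %s (last occurrence wins): %s",
                    length(dups), path, paste(utils::head(dups, 5L), collapse = ", ")),
            call. = FALSE)
    keep <- !duplicated(labels, fromLast = TRUE)
    labels <- labels[keep]
    entries <- entries[keep]
  }
  names(entries) <- labels
  structure(list(dim = dim, entries = entries), class = "embedding_store")
}

#' Write an embedding store to `.vec` format
#'
#' @param store An `embedding_store`.
#' @param path Output path.
#' @param digits Significant digits for vector components (default 8).
#' @return `path`, invisibly.
#' @export
write_vec_file <- function(store, path, digits = 8L) {
  stopifnot(inherits(store, "embedding_store"))
  body <- vapply(seq_along(store$entries), function(i) {
    paste(names(store$entries)[[i]],
          paste(formatC(store$entries[[i]], digits = digits, format = "g"),
                collapse = " "))
  }, character(1L))
  writeLines(c(paste(length(store$entries), store$dim), body),
             con = path, useBytes = FALSE)
  invisible(path)
}

#' Build an embedding store from a named list of vectors
#'
#' @param vectors Named list (or named-row matrix) of equal-length numeric
#'   vectors; names are the byte-exact lookup labels.
#' @return An `embedding_store`.
#' @export
embedding_store <- function(vectors) {
  if (is.matrix(vectors)) {
    vectors <- stats::setNames(lapply(seq_len(nrow(vectors)), function(i) vectors[i, ]),
                               rownames(vectors))
  }
  stopifnot(length(vectors) > 0L, !is.null(names(vectors)),
            all(nzchar(names(vectors))))
  lens <- lengths(vectors)
  if (length(unique(lens)) != 1L) {
    stop("all vectors must share one dimensionality", call. = FALSE)
  }
  if (anyDuplicated(names(vectors))) stop("labels must be unique", call. = FALSE)
  structure(list(dim = lens[[1L]], entries = lapply(vectors, as.numeric)),
            class = "embedding_store")
}

#' @exportS3Method base::print
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> %d entries, dim %d\n", length(x$entries), x$dim))
  invisible(x)
}

#' Character n-grams with fastText boundary markers
#'
#' Wraps `word` in `<` and `>` and returns every contiguous substring of the
#' wrapped word with length in `[minn, maxn]`, shorter n-grams first and
#' left-to-right within a length. Subword units of length 5 are the
#' composition basis used for out-of-vocabulary multi-word station labels.
#'
#' @param word Non-empty character scalar.
#' @param minn,maxn Inclusive n-gram length bounds (defaults 5, 5).
#' @return Character vector of n-grams (possibly empty when the wrapped word
#'   is shorter than `minn`).
#' @examples
#' char_ngrams("Angel")            # "<Ange" "Angel" "ngel>"
#' char_ngrams("aaa", 3, 3)
#' @export
char_ngrams <- function(word, minn = 5L, maxn = 5L) {
  stopifnot(is.character(word), length(word) == 1L, nzchar(word),
            minn >= 1L, minn <= maxn)
  wrapped <- paste0("<", word, ">")
  n <- nchar(wrapped)
  out <- character(0L)
  for (len in seq.int(minn, maxn)) {
    if (len > n) break
    starts <- seq_len(n - len + 1L)
    out <- c(out, substring(wrapped, starts, starts + len - 1L))
  }
  out
}

#' 32-bit FNV-1a hash
#'
#' The bucket hash used for subword units: offset basis 2166136261, prime
#' 16777619, per byte XOR-then-multiply, all arithmetic modulo 2^32. Operates
#' on the UTF-8 bytes of a string (or a raw vector). Returned as a double
#' because R integers cannot hold values at or above 2^31.
#'
#' @param data Character scalar (hashed as UTF-8 bytes) or raw vector.
#' @return A double in `[0, 2^32)`.
#' @examples
#' fnv1a32("")   # 2166136261, the offset basis
#' fnv1a32("a")  # 3826002220
#' @export
fnv1a32 <- function(data) {
  if (is.character(data)) {
    stopifnot(length(data) == 1L)
    data <- charToRaw(enc2utf8(data))
  }
  stopifnot(is.raw(data))
  two32 <- 4294967296
  prime <- 16777619
  h <- 2166136261
  for (b in as.integer(data)) {
    # XOR only touches the low 8 bits since b < 256
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # multiply mod 2^32 in 16-bit halves to stay inside double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% two32
  }
  h
}

#' Build a subword bucket table
#'
#' @param buckets Numeric matrix, one row per bucket index `0..bucket_count-1`;
#'   column count is the embedding dimensionality.
#' @param minn,maxn n-gram length bounds (defaults 5, 5).
#' @return A `subword_table`.
#' @export
subword_table <- function(buckets, minn = 5L, maxn = 5L) {
  buckets <- as.matrix(buckets)
  stopifnot(nrow(buckets) >= 1L, is.numeric(buckets), minn >= 1L, minn <= maxn)
  structure(list(bucket_count = nrow(buckets), buckets = buckets,
                 minn = as.integer(minn), maxn = as.integer(maxn)),
            class = "subword_table")
}

#' Bucket index of an n-gram
#'
#' @param ngram Character scalar.
#' @param bucket_count Positive number of buckets.
#' @return Integer-valued double in `[0, bucket_count)`.
#' @export
bucket_index <- function(ngram, bucket_count) {
  fnv1a32(ngram) %% bucket_count
}

#' Compose an out-of-vocabulary vector from subword n-grams
#'
#' Builds a vector for a label absent from the embedding store as an
#' aggregate of the bucket vectors of its character n-grams, each n-gram
#' mapped to a bucket by FNV-1a modulo the bucket count. The default
#' aggregate is the sum; `agg = "mean"` divides by the n-gram count, which is
#' equivalent for every cosine-based downstream quantity.
#'
#' @param word Non-empty label.
#' @param table A `subword_table`.
#' @param agg `"sum"` (default) or `"mean"`.
#' @return Numeric vector of the table's dimensionality. A word too short to
#'   produce any n-gram yields the zero vector with a warning; cosine-based
#'   consumers reject zero-norm vectors explicitly.
#' @export
oov_vector <- function(word, table, agg = c("sum", "mean")) {
  stopifnot(inherits(table, "subword_table"))
  agg <- match.arg(agg)
  grams <- char_ngrams(word, table$minn, table$maxn)
  if (length(grams) == 0L) {
    warning(sprintf("label '%s' yields no n-grams in [%d,%d]; returning zero vector",
                    word, table$minn, table$maxn), call. = FALSE)
    return(numeric(ncol(table$buckets)))
  }
  idx <- vapply(grams, bucket_index, numeric(1L), bucket_count = table$bucket_count)
  v <- colSums(table$buckets[idx + 1L, , drop = FALSE])
  if (agg == "mean") v <- v / length(grams)
  unname(v)
}

#' Cosine similarity
#'
#' @param u,v Numeric vectors of equal length with strictly positive norm.
#' @return `u.v / (|u||v|)`, in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) {
    stop("cosine undefined for zero-norm vector", call. = FALSE)
  }
  r <- sum(u * v) / (nu * nv)
  # clamp rounding spill just outside [-1, 1]
  max(-1, min(1, r))
}

#' Resolve a label to a vector, with subword fallback
#'
#' Exact (byte-identical) lookup in the store first; on a miss, subword
#' composition when a `subword_table` is supplied. The resolution route is
#' recorded in the `"provenance"` attribute (`"exact"` or `"subword"`).
#'
#' @param store An `embedding_store`.
#' @param label Non-empty label, queried exactly as written (capitalization
#'   and internal spaces preserved).
#' @param table Optional `subword_table` for out-of-vocabulary fallback.
#' @param agg Aggregation passed to [oov_vector()].
#' @return Numeric vector with attribute `provenance`.
#' @export
get_label_vector <- function(store, label, table = NULL, agg = "sum") {
  stopifnot(inherits(store, "embedding_store"), is.character(label),
            length(label) == 1L, nzchar(label))
  hit <- store$entries[[label]]
  if (!is.null(hit)) {
    return(structure(hit, provenance = "exact"))
  }
  if (is.null(table)) {
    stop("label not in embedding store and no subword table supplied: '",
         label, "'", call. = FALSE)
  }
  structure(oov_vector(label, table, agg = agg), provenance = "subword")
}

#' Serialize / read a subword table (CSV + JSON sidecar)
#'
#' The CSV holds `bucket_index,v1,...,vdim` rows; the sidecar
#' `<path>.json` holds `{bucket_count, minn, maxn}`.
#'
#' @param table A `subword_table`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `path` invisibly (write) or a `subword_table` (read).
#' @export
write_subword_table <- function(table, path) {
  stopifnot(inherits(table, "subword_table"))
  df <- data.frame(bucket_index = seq_len(table$bucket_count) - 1L,
                   table$buckets, check.names = FALSE)
  names(df) <- c("bucket_index", paste0("v", seq_len(ncol(table$buckets))))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(bucket_count = table$bucket_count,
                            minn = table$minn, maxn = table$maxn),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_subword_table
#' @export
read_subword_table <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(identical(df$bucket_index, seq_len(nrow(df)) - 1L) ||
              all(df$bucket_index == seq_len(nrow(df)) - 1L))
  subword_table(as.matrix(df[, -1L, drop = FALSE]),
                minn = meta$minn, maxn = meta$maxn)
}
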