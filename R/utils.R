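# Internal helpers shared across modules: year-month arithmetic and seed substreams.

# Parse "YYYY-MM" into c(year, month). Accepts integer vector c(year, month) unchanged.
parse_ym <- function(x) {
  if (is.numeric(x) && length(x) == 2L) {
    ym <- as.integer(x)
  } else if (is.character(x) && length(x) == 1L) {
    if (!grepl("^\\d{4}-\\d{2}$", x)) {
      stop("year-month must be 'YYYY-MM', got: ", x, call. = FALSE)
    }
    ym <- as.integer(c(substr(x, 1, 4), substr(x, 6, 7)))
  } else {
    stop("cannot interpret year-month: ", paste(x, collapse = ","), call. = FALSE)
  }
  if (ym[2L] < 1L || ym[2L] > 12L) stop("month out of range: ", ym[2L], call. = FALSE)
  ym
}

# Linear month index (months since year 0) — makes range/lag arithmetic trivial.
ym_to_index <- function(year, month) year * 12L + (month - 1L)

index_to_ym <- function(idx) {
  data.frame(year = idx %/% 12L, month = idx %% 12L + 1L)
}

# All year-months from start to end inclusive, as a data.frame(year, month).
ym_seq <- function(start, end) {
  s <- parse_ym(start)
  e <- parse_ym(end)
  i0 <- ym_to_index(s[1L], s[2L])
  i1 <- ym_to_index(e[1L], e[2L])
  if (i0 > i1) stop("period start is after period end", call. = FALSE)
  index_to_ym(seq.int(i0, i1))
}

ym_label <- function(year, month) sprintf("%04d-%02d", year, month)

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  as.integer(seq(first, by = "1 month", length.out = 2L)[2L] - first)
}

# Deterministic per-component seed substream derived from one global seed.
# Keeps every derived seed a valid 32-bit integer.
substream_seed <- function(seed, component) {
  offsets <- c(
    facilities = 101L, grid = 211L, counts = 307L, missingness = 401L,
    closures = 503L, scenario = 601L
  )
  off <- offsets[[component]]
  if (is.null(off)) stop("unknown seed substream: ", component, call. = FALSE)
  as.integer((as.double(seed) * 48271 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
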