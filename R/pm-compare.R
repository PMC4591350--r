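#' Activity-difference specificity statistic between two strains
#'
#' For a shared substrate list, computes per-substrate activity
#' differences `delta_a = a_strain2 - a_strain1`, their mean `mu_a` and
#' sample standard deviation `sigma_a` (n - 1 denominator), and calls
#' each substrate strain-specific when its difference falls beyond the
#' sigma band:
#' \describe{
#'   \item{zero centering (default)}{strain1-specific iff
#'     `delta_a < -sigma_a`; strain2-specific iff `delta_a > +sigma_a`;
#'     otherwise shared — the literal reading of the published rule;}
#'   \item{mean centering}{the cutpoints are `mu_a - sigma_a` and
#'     `mu_a + sigma_a`, matching the plotted band lines; the two
#'     readings disagree whenever `mu_a != 0`.}
#' }
#' `sigma_a = 0` makes every substrate shared. Calls carry the actual
#' strain ids (or `"shared"`).
#'
#' @param a1,a2 Named numeric activity vectors for strain 1 and
#'   strain 2 over the identical substrate list (>= 2 substrates).
#' @param strain1,strain2 Strain ids used in the calls.
#' @param centering `"zero"` or `"mean"`.
#' @return A list of class `DeltaA`: `table` (data.frame `substrate`,
#'   `a_strain1`, `a_strain2`, `delta_a`, `call`), `mu_a`, `sigma_a`,
#'   `centering`, `strain1`, `strain2`.
#' @examples
#' da <- delta_a_classify(c(s1 = 10, s2 = 0, s3 = 5, s4 = 5, s5 = 5),
#'                        c(s1 = 0, s2 = 10, s3 = 5, s4 = 5, s5 = 5))
#' da$sigma_a   # sqrt(50)
#' da$table$call
#' @export
delta_a_classify <- function(a1, a2, strain1 = "strain1", strain2 = "strain2",
                             centering = c("zero", "mean")) {
  centering <- match.arg(centering)
  if (is.null(names(a1)) || is.null(names(a2)))
    stop_("activity vectors must be named by substrate")
  if (length(a1) != length(a2) || !identical(names(a1), names(a2)))
    stop_("substrate lists differ between strains (pairing error)")
  if (length(a1) < 2L) stop_("at least two substrates are required for sigma_a")
  delta <- unname(a2 - a1)
  mu <- mean(delta)
  sigma <- sd(delta)
  centre <- if (centering == "zero") 0 else mu
  call <- rep("shared", length(delta))
  if (sigma > 0) {
    call[delta < centre - sigma] <- strain1
    call[delta > centre + sigma] <- strain2
  }
  structure(list(
    table = data.frame(substrate = names(a1), a_strain1 = unname(a1),
                       a_strain2 = unname(a2), delta_a = delta, call = call,
                       stringsAsFactors = FALSE),
    mu_a = mu, sigma_a = sigma, centering = centering,
    strain1 = strain1, strain2 = strain2), class = "DeltaA")
}

#' @export
print.DeltaA <- function(x, ...) {
  cat(sprintf("DeltaA (%s vs %s, %s-centred): mu_a = %.4g, sigma_a = %.4g\n",
              x$strain1, x$strain2, x$centering, x$mu_a, x$sigma_a))
  print(table(x$table$call))
  invisible(x)
}

#' Scatter table with sigma band offsets
#'
#' Per-substrate activities of the two strains plus the offsets of the
#' five diagonal band lines `y = x + offset` (mean, mean +/- sigma,
#' mean +/- 2 sigma) that reproduce the published scatter plot.
#'
#' @param da A `DeltaA` result.
#' @return A list with `table` (`substrate`, `a_strain1`, `a_strain2`)
#'   and `offsets` (named numeric vector `mu-2s, mu-s, mu, mu+s, mu+2s`).
#' @export
scatter_table <- function(da) {
  if (!inherits(da, "DeltaA")) stop_("scatter_table expects a DeltaA result")
  offs <- c(da$mu_a - 2 * da$sigma_a, da$mu_a - da$sigma_a, da$mu_a,
            da$mu_a + da$sigma_a, da$mu_a + 2 * da$sigma_a)
  names(offs) <- c("mu-2sigma", "mu-sigma", "mu", "mu+sigma", "mu+2sigma")
  list(table = da$table[, c("substrate", "a_strain1", "a_strain2")],
       offsets = offs)
}

EC_PATTERN <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.(n?[0-9]+|-)$"

norm_substrate <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Read a substrate-to-EC mapping table
#'
#' Dialect: `substrate<TAB>EC;EC,...` with EC codes separated by commas
#' or semicolons; the literal value `unknown` (or an empty field) means
#' no enzyme is known for the substrate. Malformed EC tokens are a
#' parse error naming the row.
#'
#' @param path TSV path.
#' @return A named list: substrate (normalized) -> character vector of
#'   EC codes (possibly empty).
#' @export
read_ec_mapping <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  out <- list()
  raw_names <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 1L || !nzchar(trimws(f[1])))
      stop_("EC mapping parse error at row %d: missing substrate", i)
    ecs <- if (length(f) < 2L) character(0) else {
      toks <- trimws(strsplit(f[2], "[,;]")[[1]])
      toks <- toks[nzchar(toks)]
      if (length(toks) == 1L && tolower(toks) == "unknown") character(0)
      else {
        bad <- toks[!grepl(EC_PATTERN, toks)]
        if (length(bad))
          stop_("EC mapping parse error at row %d: malformed EC token '%s'",
                i, bad[1])
        toks
      }
    }
    out[[norm_substrate(f[1])]] <- ecs
    raw_names <- c(raw_names, f[1])
  }
  attr(out, "raw_names") <- raw_names
  out
}

#' Associate substrates with enzyme EC codes
#'
#' Looks up each substrate (case-insensitively, after whitespace
#' normalization) in a substrate-to-EC mapping; substrates without a
#' mapping row, or mapped to no enzyme, get the literal label
#' `"unknown"`.
#'
#' @param substrates Character vector of substrate names.
#' @param mapping A mapping from [read_ec_mapping()] (or a named list of
#'   EC code vectors).
#' @return A data.frame with `substrate` and `ec_codes` (semicolon-joined
#'   codes or `"unknown"`), plus list-column `ec_list`.
#' @export
ec_association <- function(substrates, mapping) {
  if (!length(substrates))
    return(data.frame(substrate = character(), ec_codes = character(),
                      stringsAsFactors = FALSE))
  keys <- norm_substrate(substrates)
  ec_list <- lapply(keys, function(k) mapping[[k]] %||% character(0))
  data.frame(substrate = substrates,
             ec_codes = vapply(ec_list, function(e)
               if (length(e)) paste(e, collapse = "; ") else "unknown",
               character(1)),
             ec_list = I(ec_list),
             stringsAsFactors = FALSE)
}
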