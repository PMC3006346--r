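## Taxon codes used throughout: F = forest elephant, S = savanna elephant,
## A = Asian elephant, M = woolly mammoth, O = mastodon (outgroup).

#' Elephantid and outgroup taxon codes
#'
#' The five taxa of the study system. `F`, `S`, `A`, `M` are the diploid
#' elephantids (two chromosomes sampled per taxon); `O` is the haploid
#' mastodon outgroup used for polarization.
#'
#' @format Character vectors of single-letter taxon codes.
#' @export
ELEPHANTID_TAXA <- c("F", "S", "A", "M")

#' @rdname ELEPHANTID_TAXA
#' @export
ALL_TAXA <- c("F", "S", "A", "M", "O")

#' @rdname ELEPHANTID_TAXA
#' @export
AFRICAN_TAXA <- c("F", "S")

#' @rdname ELEPHANTID_TAXA
#' @export
EURASIAN_TAXA <- c("A", "M")

#' Clade of a taxon code
#'
#' @param code character vector of taxon codes.
#' @return character vector in `{"African","Eurasian","outgroup"}`.
#' @export
taxon_clade <- function(code) {
  stopifnot(all(code %in% ALL_TAXA))
  ifelse(code %in% AFRICAN_TAXA, "African",
         ifelse(code %in% EURASIAN_TAXA, "Eurasian", "outgroup"))
}

## number of chromosomes sampled per taxon
taxon_ploidy <- function(code) ifelse(code == "O", 1L, 2L)

#' Default sample-to-taxon mapping
#'
#' Maps the simulator's sample labels (`F_1`, `F_2`, ..., `O`) to taxon
#' codes. Labels of user data can follow any scheme as long as an explicit
#' map is supplied to the readers.
#'
#' @return named character vector, names = sample labels, values = taxon codes.
#' @export
default_sample_map <- function() {
  labs <- c(paste(rep(ELEPHANTID_TAXA, each = 2), 1:2, sep = "_"), "O")
  setNames(c(rep(ELEPHANTID_TAXA, each = 2), "O"), labs)
}
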