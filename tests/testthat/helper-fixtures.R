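# shared fixture loaders and small constructors used across test files

maleCounts <- function() c(228, 116, 51, 35, 22, 11, 5, 3, 2, 1)
femaleCounts <- function() c(353, 171, 73, 55, 36, 18, 8, 6, 5, 2, 1)

femaleExpectancyTable <- function() {
  read.delim(pikaExtdata("expectancy_female_radix1000.tsv"))
}

reproValueTable <- function() {
  read.delim(pikaExtdata("reproductive_value_female.tsv"))
}

adultTripleCatch <- function() {
  readTripleCatch(pikaExtdata("adult_triple_catch.tsv"))
}

pikaTraits <- function() {
  read.delim(pikaExtdata("life_history_traits.tsv"), na.strings = "\u25cf",
             fileEncoding = "UTF-8")
}

traitValue <- function(trait, column = "pooled") {
  tb <- pikaTraits()
  tb[tb$trait == trait, column]
}

# random non-increasing positive integer cohort for property tests
randomCohort <- function(nClasses = sample(3:12, 1), n0 = sample(50:500, 1)) {
  s <- runif(nClasses - 1, 0.3, 0.95)
  alive <- round(n0 * cumprod(c(1, s)))
  alive <- alive[alive > 0]
  if (length(alive) < 2) alive <- c(max(alive, 2), 1)
  alive
}
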