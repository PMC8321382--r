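# Shared fixtures, built in code.

# Imageless marks dataset with the requested per-class counts; enough for
# every counting/splitting/balancing operation (none of which touch pixels).
make_count_dataset <- function(counts) {
  marks <- do.call(rbind, lapply(names(counts), function(cl) {
    n <- counts[[cl]]
    if (n == 0) return(NULL)
    data.frame(image_id = sprintf("%s_%05d", gsub("-", "", cl), seq_len(n)),
               x = 45L, y = 45L, label = cl, stringsAsFactors = FALSE)
  }))
  cyto_dataset(marks)
}

# A deterministic asymmetric patch (no nontrivial symmetry), for checking
# that geometric transforms are distinct exact permutations.
asym_patch <- function(n = 3) matrix(seq_len(n * n)^1.3, n, n)

# Independent majority-with-tiebreak rule, coded from scratch for the vote
# oracle: count votes; unique plurality wins; otherwise scan members in
# rank order and take the first whose vote is among the leading classes.
brute_vote <- function(votes, classes) {
  counts <- sapply(classes, function(cl) sum(votes == cl))
  lead <- classes[counts == max(counts)]
  if (length(lead) == 1) return(lead)
  for (v in votes) if (v %in% lead) return(v)
}
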