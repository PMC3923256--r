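# 32-bit FNV-1a over integer token streams, in exact double arithmetic.
# Used to map substructure features to fingerprint positions; a fixed,
# platform-independent hash keeps fingerprints reproducible across machines.

FNV_OFFSET <- 2166136261
FNV_PRIME <- 16777619
TWO32 <- 4294967296

xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}

# (a * b) mod 2^32 without exceeding the exact-double range
mul32 <- function(a, b) {
  (((a * (b %/% 65536)) %% 65536) * 65536 + a * (b %% 65536)) %% TWO32
}

# hash one non-negative integer token vector to [0, 2^32)
hash_tokens <- function(tokens) {
  h <- FNV_OFFSET
  for (t in tokens) {
    h <- mul32(xor32(h, t %% TWO32), FNV_PRIME)
  }
  h
}

# stable hash of a character scalar (config fingerprinting, manifests)
hash_string <- function(x) {
  h <- hash_tokens(utf8ToInt(x))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
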