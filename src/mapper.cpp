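#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <set>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode a base; -1 for anything not ACGT
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int32_t,int32_t> > > KmerIndex;

// Map reads against genomes with exact k-mer seeding and ungapped extension
// over the full read.  Reads overhanging a genome end are scored on the
// overlapping part only.  Returns all hits with percent identity >=
// min_identity; the best-hit flag is assigned in R.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector genomes,
                        int k, double min_identity, int stride) {
  if (k < 1 || k > 31) stop("seed_k must be between 1 and 31");
  if (stride < 1) stop("stride must be >= 1");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // build index over all genome k-mers
  KmerIndex index;
  std::vector<std::string> gseq(genomes.size());
  for (int g = 0; g < genomes.size(); ++g) {
    gseq[g] = as<std::string>(genomes[g]);
    const std::string& s = gseq[g];
    if ((int)s.size() < k) continue;
    uint64_t h = 0; int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++valid >= k)
        index[h].push_back(std::make_pair((int32_t)g, (int32_t)(i + 1 - k)));
    }
  }

  std::vector<int> out_read, out_genome, out_start, out_end,
                   out_matches, out_alen;
  std::vector<int> out_strand; // 1 = forward, 0 = reverse

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int L = (int)fwd.size();
    if (L < k) continue;
    std::string rev(L, 'N');
    for (int i = 0; i < L; ++i) rev[L - 1 - i] = comp(fwd[i]);

    // candidate placements: (genome, genome offset of read start, strand)
    std::set<std::tuple<int,int,int> > cand;
    for (int strand = 1; strand >= 0; --strand) {
      const std::string& s = strand ? fwd : rev;
      uint64_t h = 0; int valid = 0;
      for (int i = 0; i < L; ++i) {
        int b = base2bit(s[i]);
        if (b < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        if (valid + 1 >= k && ((i + 1 - k) % stride == 0)) {
          KmerIndex::const_iterator it = index.find(h);
          if (it != index.end()) {
            for (size_t m = 0; m < it->second.size(); ++m) {
              int g = it->second[m].first;
              int off = it->second[m].second - (i + 1 - k);
              if (cand.size() < 512)
                cand.insert(std::make_tuple(g, off, strand));
            }
          }
        }
        ++valid;
      }
    }

    for (std::set<std::tuple<int,int,int> >::iterator it = cand.begin();
         it != cand.end(); ++it) {
      int g = std::get<0>(*it), off = std::get<1>(*it),
          strand = std::get<2>(*it);
      const std::string& gs = gseq[g];
      const std::string& rs = strand ? fwd : rev;
      int astart = off > 0 ? off : 0;
      int aend = std::min((int)gs.size(), off + L);
      int alen = aend - astart;
      if (alen < k) continue;
      int matches = 0;
      for (int p = astart; p < aend; ++p) {
        char a = gs[p], b = rs[p - off];
        if (a >= 'a') a -= 32;
        if (b >= 'a') b -= 32;
        if (a == b) ++matches;
      }
      double pid = 100.0 * matches / alen;
      if (pid >= min_identity) {
        out_read.push_back(r + 1);
        out_genome.push_back(g + 1);
        out_start.push_back(astart);
        out_end.push_back(aend);
        out_strand.push_back(strand);
        out_matches.push_back(matches);
        out_alen.push_back(alen);
      }
    }
  }

  return DataFrame::create(
    Named("read_idx") = out_read,
    Named("genome_idx") = out_genome,
    Named("start") = out_start,
    Named("end") = out_end,
    Named("forward") = out_strand,
    Named("matches") = out_matches,
    Named("aligned_length") = out_alen);
}

// Leading/trailing low-quality trim bounds (1-based, inclusive); 0,0 when the
// whole read falls below the threshold.
// [[Rcpp::export]]
IntegerMatrix cpp_trim_bounds(CharacterVector quals, int min_char) {
  IntegerMatrix out(quals.size(), 2);
  for (int i = 0; i < quals.size(); ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    int n = (int)LENGTH(STRING_ELT(quals, i));
    int lo = 0;
    while (lo < n && (int)(unsigned char)q[lo] < min_char) ++lo;
    int hi = n - 1;
    while (hi >= lo && (int)(unsigned char)q[hi] < min_char) --hi;
    if (lo > hi) { out(i, 0) = 0; out(i, 1) = 0; }
    else { out(i, 0) = lo + 1; out(i, 1) = hi + 1; }
  }
  return out;
}
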