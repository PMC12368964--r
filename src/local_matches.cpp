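#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Gap-free seed-and-extend local matching between two DNA strings.
// Seeds are exact k-mer matches; seeds on one diagonal closer than max_gap
// are merged into one gap-free fragment, whose ends are then extended while
// bases agree. Identity is computed over every column of the final span.

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1; // N or other: breaks k-mers
  }
}

static void kmer_positions(const std::string& s, int k,
                           std::unordered_map<uint64_t, std::vector<int> >& idx,
                           int max_occ) {
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0;
  int valid = 0; // run of non-N bases ending at i
  for (int i = 0; i < n; ++i) {
    int c = base2code(s[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      std::vector<int>& v = idx[h];
      if ((int)v.size() < max_occ) v.push_back(i - k + 1);
    }
  }
}

struct Frag { int a_start, a_end, b_start, b_end, matches; double identity; };

// core: one strand, returns fragments in (a, b') coordinates where b' is the
// possibly reverse-complemented copy of b.
static std::vector<Frag> match_one(const std::string& a, const std::string& b,
                                   int k, int min_len, double min_identity,
                                   int max_gap, int max_occ) {
  std::vector<Frag> out;
  const int na = (int)a.size(), nb = (int)b.size();
  if (na < k || nb < k) return out;

  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve(na * 2);
  kmer_positions(a, k, idx, max_occ);

  // collect seed hits grouped by diagonal (j - i)
  std::unordered_map<long, std::vector<int> > diag_hits; // diag -> a-positions
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int valid = 0;
  for (int j = 0; j < nb; ++j) {
    int c = base2code(b[j]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(h);
      if (it != idx.end()) {
        int jstart = j - k + 1;
        const std::vector<int>& v = it->second;
        for (size_t m = 0; m < v.size(); ++m)
          diag_hits[(long)jstart - (long)v[m]].push_back(v[m]);
      }
    }
  }

  for (std::unordered_map<long, std::vector<int> >::iterator it = diag_hits.begin();
       it != diag_hits.end(); ++it) {
    long diag = it->first;
    std::vector<int>& pos = it->second;
    std::sort(pos.begin(), pos.end());
    size_t i0 = 0;
    while (i0 < pos.size()) {
      int span_start = pos[i0];
      int span_end = pos[i0] + k; // half-open on a
      size_t i1 = i0 + 1;
      while (i1 < pos.size() && pos[i1] <= span_end + max_gap) {
        span_end = std::max(span_end, pos[i1] + k);
        ++i1;
      }
      // greedy exact extension
      int as = span_start, ae = span_end;
      while (as > 0 && as + diag > 0 && a[as - 1] == b[as - 1 + diag] &&
             base2code(a[as - 1]) >= 0) --as;
      while (ae < na && ae + diag < nb && a[ae] == b[ae + diag] &&
             base2code(a[ae]) >= 0) ++ae;
      int len = ae - as;
      if (len >= min_len) {
        int matches = 0;
        for (int p = as; p < ae; ++p)
          if (a[p] == b[p + diag] && base2code(a[p]) >= 0) ++matches;
        double ident = (double)matches / (double)len;
        if (ident >= min_identity) {
          Frag f; f.a_start = as; f.a_end = ae;
          f.b_start = as + (int)diag; f.b_end = ae + (int)diag;
          f.matches = matches; f.identity = ident;
          out.push_back(f);
        }
      }
      i0 = i1;
    }
  }
  return out;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break; case 'a': r[i] = 't'; break;
      case 'C': r[i] = 'G'; break; case 'c': r[i] = 'g'; break;
      case 'G': r[i] = 'C'; break; case 'g': r[i] = 'c'; break;
      case 'T': r[i] = 'A'; break; case 't': r[i] = 'a'; break;
      default: break;
    }
  }
  return r;
}

// [[Rcpp::export(name = ".local_matches_cpp")]]
DataFrame local_matches_cpp(std::string a, std::string b, int k, int min_len,
                            double min_identity, int max_gap, int max_occ,
                            bool do_plus, bool do_minus) {
  std::vector<Frag> plus, minus;
  if (do_plus) plus = match_one(a, b, k, min_len, min_identity, max_gap, max_occ);
  if (do_minus) {
    std::string brc = revcomp(b);
    minus = match_one(a, brc, k, min_len, min_identity, max_gap, max_occ);
  }
  const int nb = (int)b.size();
  int n = (int)(plus.size() + minus.size());
  IntegerVector a_start(n), a_end(n), b_start(n), b_end(n), matches(n), length(n);
  NumericVector identity(n);
  CharacterVector strand(n);
  int r = 0;
  for (size_t i = 0; i < plus.size(); ++i, ++r) {
    a_start[r] = plus[i].a_start; a_end[r] = plus[i].a_end;
    b_start[r] = plus[i].b_start; b_end[r] = plus[i].b_end;
    matches[r] = plus[i].matches; identity[r] = plus[i].identity;
    length[r] = plus[i].a_end - plus[i].a_start; strand[r] = "+";
  }
  for (size_t i = 0; i < minus.size(); ++i, ++r) {
    // map coordinates on revcomp(b) back onto b
    a_start[r] = minus[i].a_start; a_end[r] = minus[i].a_end;
    b_start[r] = nb - minus[i].b_end; b_end[r] = nb - minus[i].b_start;
    matches[r] = minus[i].matches; identity[r] = minus[i].identity;
    length[r] = minus[i].a_end - minus[i].a_start; strand[r] = "-";
  }
  return DataFrame::create(
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end,
    _["strand"] = strand, _["length"] = length,
    _["matches"] = matches, _["identity"] = identity,
    _["stringsAsFactors"] = false);
}
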