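#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Spliced decomposition of a genomic amplicon against its cDNA.
//
// Model: the amplicon is tiled by alternating exons and introns, starting and
// ending with an exon; exons align to the cDNA with substitutions only (no
// indels); introns are genomic-only gaps of length >= minIntron.
// Scoring: match +1, mismatch -1, intron opening -8, +4 bonus when the intron
// is canonical (GT donor, AG acceptor). The canonical bonus dominates the
// positional tie-break so that GT..AG placements win whenever one exists;
// residual placement ambiguity is normalised on the R side (leftmost rule).
//
// [[Rcpp::export]]
List cpp_spliced_align(std::string g, std::string c, int minIntron) {
  const int n = (int) g.size(), m = (int) c.size();
  const int MATCH = 1, MISMATCH = -1, OPEN = -8, CANON = 4;
  const int NEG = -1000000000;
  if (m > n) stop("cDNA longer than genomic sequence");
  std::vector<int> S((size_t)(n + 1) * (m + 1), NEG);
  std::vector<signed char> bp((size_t)(n + 1) * (m + 1), 0);  // 0 none, 1 diag, 2 intron
  std::vector<int> ist((size_t)(n + 1) * (m + 1), -1);        // intron: genomic consumed before it
  std::vector<int> bestAny(m + 1, NEG), bestAnyI(m + 1, -1);
  std::vector<int> bestDon(m + 1, NEG), bestDonI(m + 1, -1);
  // running maxima only ever admit states that end in an aligned (exonic)
  // column, so two introns can never be adjacent
  auto at = [&](int i, int j) -> size_t { return (size_t) i * (m + 1) + j; };
  S[at(0, 0)] = 0;
  for (int i = 1; i <= n; i++) {
    int ip = i - minIntron;  // candidate exon end feeding an intron that closes at i
    if (ip >= 1) {
      bool donor = (ip + 1 < n) && g[ip] == 'G' && g[ip + 1] == 'T';
      for (int j = 1; j < m; j++) {
        int v = S[at(ip, j)];
        if (v > NEG && bp[at(ip, j)] == 1) {
          if (v > bestAny[j]) { bestAny[j] = v; bestAnyI[j] = ip; }
          if (donor && v > bestDon[j]) { bestDon[j] = v; bestDonI[j] = ip; }
        }
      }
    }
    bool acceptor = (i >= 2) && g[i - 2] == 'A' && g[i - 1] == 'G';
    for (int j = (i > n - m ? i - (n - m) : 0); j <= m && j <= i; j++) {
      int best = NEG; signed char b = 0; int isrc = -1;
      if (j > 0) {
        int v = S[at(i - 1, j - 1)];
        if (v > NEG) {
          v += (g[i - 1] == c[j - 1] ? MATCH : MISMATCH);
          if (v > best) { best = v; b = 1; }
        }
      }
      if (j >= 1 && j < m) {  // an intron must sit between non-empty exons
        int v1 = bestAny[j] > NEG ? bestAny[j] + OPEN : NEG;
        int v2 = (acceptor && bestDon[j] > NEG) ? bestDon[j] + OPEN + CANON : NEG;
        if (v2 >= v1) {
          if (v2 > best) { best = v2; b = 2; isrc = bestDonI[j]; }
        } else {
          if (v1 > best) { best = v1; b = 2; isrc = bestAnyI[j]; }
        }
      }
      if (b != 0) { S[at(i, j)] = best; bp[at(i, j)] = b; ist[at(i, j)] = isrc; }
    }
  }
  if (S[at(n, m)] <= NEG)
    return List::create(_["score"] = IntegerVector::create(NA_INTEGER));
  // traceback
  std::vector<int> istart, iend;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char b = bp[at(i, j)];
    if (b == 1) { i--; j--; }
    else if (b == 2) {
      int ip = ist[at(i, j)];
      istart.push_back(ip + 1);  // 1-based genomic start of intron
      iend.push_back(i);
      i = ip;
    } else stop("traceback failure");
  }
  std::reverse(istart.begin(), istart.end());
  std::reverse(iend.begin(), iend.end());
  return List::create(_["score"] = S[at(n, m)],
                      _["intron_start"] = wrap(istart),
                      _["intron_end"] = wrap(iend));
}
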