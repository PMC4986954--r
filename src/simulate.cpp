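// Forward-in-time gene-dropping over origin-labelled chromosome segments.
//
// A haploid genome is, per chromosome, a list of half-open segments
// [start, end) labelled with the founder-haplotype row they descend from,
// plus a sorted list of site indices whose inherited allele must be
// flipped (accumulated mutations; a second hit at the same site toggles
// the flip off again).  Storage grows with crossover/mutation events, not
// with site count; founder sequence is only materialised by cpp_drop().
//
// All randomness goes through R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct ChromSeg {
  std::vector<double> ends;  // segment end positions, last == chrom length
  std::vector<int> orig;     // 1-based founder haplotype row per segment
  std::vector<int> mut;      // sorted 1-based global site indices to flip
};

typedef std::vector<ChromSeg> Homolog;  // one entry per chromosome

struct Indiv {
  Homolog h1, h2;
};

struct MapInfo {
  std::vector<double> len;               // chromosome genetic lengths (M)
  std::vector<std::vector<double> > pos; // per-chrom site positions
  std::vector<int> offset;               // 0-based global index of first site
  int n_chrom;
  int n_sites;
};

static MapInfo parse_map(const List& map) {
  MapInfo m;
  NumericVector len = map["lengths"];
  List pos = map["pos"];
  m.n_chrom = len.size();
  m.len.assign(len.begin(), len.end());
  m.n_sites = 0;
  for (int c = 0; c < m.n_chrom; ++c) {
    NumericVector pc = pos[c];
    m.pos.push_back(std::vector<double>(pc.begin(), pc.end()));
    m.offset.push_back(m.n_sites);
    m.n_sites += pc.size();
  }
  return m;
}

static ChromSeg parse_chromseg(const List& x) {
  ChromSeg cs;
  NumericVector e = x["ends"];
  IntegerVector o = x["origin"];
  IntegerVector mu = x["mut"];
  cs.ends.assign(e.begin(), e.end());
  cs.orig.assign(o.begin(), o.end());
  cs.mut.assign(mu.begin(), mu.end());
  return cs;
}

static Homolog parse_homolog(const List& x) {
  Homolog h;
  for (int c = 0; c < x.size(); ++c) h.push_back(parse_chromseg(x[c]));
  return h;
}

static Indiv parse_indiv(const List& x) {
  Indiv ind;
  ind.h1 = parse_homolog(x[0]);
  ind.h2 = parse_homolog(x[1]);
  return ind;
}

static List wrap_chromseg(const ChromSeg& cs) {
  return List::create(_["ends"] = NumericVector(cs.ends.begin(), cs.ends.end()),
                      _["origin"] = IntegerVector(cs.orig.begin(), cs.orig.end()),
                      _["mut"] = IntegerVector(cs.mut.begin(), cs.mut.end()));
}

static List wrap_homolog(const Homolog& h) {
  List out(h.size());
  for (size_t c = 0; c < h.size(); ++c) out[c] = wrap_chromseg(h[c]);
  return out;
}

static List wrap_indiv(const Indiv& ind) {
  return List::create(wrap_homolog(ind.h1), wrap_homolog(ind.h2));
}

// Copy [a, b) from source chromosome into the gamete, merging contiguous
// same-origin segments and carrying mutation flips that fall inside.
static void copy_interval(ChromSeg& out, const ChromSeg& src,
                          const std::vector<double>& sitepos,
                          int offset, double a, double b) {
  if (b <= a) return;
  double start = 0.0;
  for (size_t s = 0; s < src.ends.size(); ++s) {
    double segs = start, sege = src.ends[s];
    start = sege;
    double lo = std::max(segs, a), hi = std::min(sege, b);
    if (hi <= lo) continue;
    if (!out.orig.empty() && out.orig.back() == src.orig[s]) {
      out.ends.back() = hi;  // extend contiguous same-origin run
    } else {
      out.ends.push_back(hi);
      out.orig.push_back(src.orig[s]);
    }
  }
  // mutations with position in [a, b)
  for (size_t k = 0; k < src.mut.size(); ++k) {
    int g = src.mut[k];                 // 1-based global index
    double p = sitepos[g - 1 - offset];
    bool last = (b >= src.ends.back());
    if (p >= a && (p < b || (last && p <= b))) out.mut.push_back(g);
  }
}

// One meiosis of a diploid parent: crossover count ~ Poisson(length),
// uniform positions, no interference; fair-coin starting homolog; new
// mutations flip allele state at panel sites with prob mu each.
static Homolog meiosis(const Indiv& parent, const MapInfo& map, double mu,
                       int* n_crossovers) {
  Homolog gam(map.n_chrom);
  for (int c = 0; c < map.n_chrom; ++c) {
    double L = map.len[c];
    const ChromSeg& s1 = parent.h1[c];
    const ChromSeg& s2 = parent.h2[c];
    int ncx = (L > 0.0) ? (int) R::rpois(L) : 0;
    if (n_crossovers) *n_crossovers += ncx;
    std::vector<double> bp(ncx);
    for (int i = 0; i < ncx; ++i) bp[i] = unif_rand() * L;
    std::sort(bp.begin(), bp.end());
    bp.push_back(L);
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    ChromSeg& out = gam[c];
    double a = 0.0;
    for (size_t i = 0; i < bp.size(); ++i) {
      const ChromSeg& src = (cur == 0) ? s1 : s2;
      copy_interval(out, src, map.pos[c], map.offset[c], a, bp[i]);
      a = bp[i];
      cur = 1 - cur;
    }
    std::sort(out.mut.begin(), out.mut.end());
    // de novo mutations: toggle membership in the flip set
    int nsite = (int) map.pos[c].size();
    if (mu > 0.0 && nsite > 0) {
      int nmut = (int) R::rbinom((double) nsite, mu);
      for (int i = 0; i < nmut; ++i) {
        int g = map.offset[c] + 1 + (int) (unif_rand() * nsite);
        if (g > map.offset[c] + nsite) g = map.offset[c] + nsite;
        std::vector<int>::iterator it =
          std::lower_bound(out.mut.begin(), out.mut.end(), g);
        if (it != out.mut.end() && *it == g) out.mut.erase(it);
        else out.mut.insert(it, g);
      }
    }
  }
  return gam;
}

// [[Rcpp::export]]
List cpp_make_gamete(List parent, List map, double mu) {
  RNGScope scope;
  MapInfo m = parse_map(map);
  Indiv p = parse_indiv(parent);
  int ncx = 0;
  Homolog g = meiosis(p, m, mu, &ncx);
  List out = wrap_homolog(g);
  out.attr("crossovers") = ncx;
  return out;
}

static std::vector<Indiv> parse_pop(const List& pop) {
  std::vector<Indiv> v;
  v.reserve(pop.size());
  for (int i = 0; i < pop.size(); ++i) v.push_back(parse_indiv(pop[i]));
  return v;
}

static List wrap_pop(const std::vector<Indiv>& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = wrap_indiv(v[i]);
  return out;
}

static std::vector<Indiv> next_gen(const std::vector<Indiv>& cur, int n_off,
                                   const MapInfo& m, double mu) {
  std::vector<Indiv> off(n_off);
  int N = (int) cur.size();
  for (int i = 0; i < n_off; ++i) {
    int p1 = (int) (unif_rand() * N); if (p1 == N) --p1;
    int p2 = (int) (unif_rand() * N); if (p2 == N) --p2;
    off[i].h1 = meiosis(cur[p1], m, mu, 0);
    off[i].h2 = meiosis(cur[p2], m, mu, 0);
  }
  return off;
}

// [[Rcpp::export]]
List cpp_next_generation(List pop, int n_offspring, List map, double mu) {
  RNGScope scope;
  MapInfo m = parse_map(map);
  std::vector<Indiv> cur = parse_pop(pop);
  return wrap_pop(next_gen(cur, n_offspring, m, mu));
}

// Evolve from a founder panel: generation 1 = pop_size offspring of the
// founders (2 * pop_size founder gametes, each a meiosis of one founder's
// two phased haplotypes), then random mating for the remaining
// generations.  Only generations listed in `snapshots` are returned.
// [[Rcpp::export]]
List cpp_evolve(int n_founders, List map, int pop_size, int n_generations,
                double mu, IntegerVector snapshots) {
  RNGScope scope;
  MapInfo m = parse_map(map);
  // founders as diploids whose homologs are single full-length segments
  std::vector<Indiv> cur(n_founders);
  for (int i = 0; i < n_founders; ++i) {
    for (int c = 0; c < m.n_chrom; ++c) {
      ChromSeg a, b;
      a.ends.push_back(m.len[c]); a.orig.push_back(2 * i + 1);
      b.ends.push_back(m.len[c]); b.orig.push_back(2 * i + 2);
      cur[i].h1.push_back(a);
      cur[i].h2.push_back(b);
    }
  }
  std::vector<int> snap(snapshots.begin(), snapshots.end());
  List out(snap.size());
  for (int g = 1; g <= n_generations; ++g) {
    cur = next_gen(cur, pop_size, m, mu);
    for (size_t k = 0; k < snap.size(); ++k) {
      if (snap[k] == g) out[k] = wrap_pop(cur);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Materialise genotypes (0/1/2, allele-1 counts) at the requested sites by
// dropping founder sequence through the recorded segments and flips.
// `sites` are sorted 1-based global site indices.
// [[Rcpp::export]]
IntegerMatrix cpp_drop(List pop, IntegerMatrix alleles, List map,
                       IntegerVector sites) {
  MapInfo m = parse_map(map);
  int n = pop.size(), ns = sites.size();
  IntegerMatrix G(n, ns);
  // per-chromosome views of the requested sites
  std::vector<std::vector<int> > colidx(m.n_chrom);  // output column
  std::vector<std::vector<double> > colpos(m.n_chrom);
  std::vector<std::vector<int> > colglob(m.n_chrom);
  for (int j = 0; j < ns; ++j) {
    int g = sites[j];
    int c = m.n_chrom - 1;
    while (c > 0 && g <= m.offset[c]) --c;
    colidx[c].push_back(j);
    colglob[c].push_back(g);
    colpos[c].push_back(m.pos[c][g - 1 - m.offset[c]]);
  }
  for (int i = 0; i < n; ++i) {
    Indiv ind = parse_indiv(pop[i]);
    for (int hh = 0; hh < 2; ++hh) {
      const Homolog& h = (hh == 0) ? ind.h1 : ind.h2;
      for (int c = 0; c < m.n_chrom; ++c) {
        const ChromSeg& cs = h[c];
        const std::vector<int>& ci = colidx[c];
        if (ci.empty()) continue;
        const std::vector<double>& cp = colpos[c];
        size_t seg = 0;
        double start = 0.0;
        for (size_t k = 0; k < ci.size(); ++k) {
          double p = cp[k];
          while (seg + 1 < cs.ends.size() && p >= cs.ends[seg]) {
            start = cs.ends[seg];
            ++seg;
          }
          (void) start;  // site at the terminal position joins last segment
          int a = alleles(cs.orig[seg] - 1, colglob[c][k] - 1);
          G(i, ci[k]) += a;
        }
        // apply accumulated flips at requested sites
        for (size_t q = 0; q < cs.mut.size(); ++q) {
          int g = cs.mut[q];
          std::vector<int>::const_iterator it =
            std::lower_bound(colglob[c].begin(), colglob[c].end(), g);
          if (it != colglob[c].end() && *it == g) {
            int j = ci[it - colglob[c].begin()];
            // flipping one homolog changes the count by +1/-1; recover the
            // homolog's inherited allele from the segment covering it
            size_t s2 = 0; double st = 0.0;
            double p = m.pos[c][g - 1 - m.offset[c]];
            while (s2 + 1 < cs.ends.size() && p >= cs.ends[s2]) {
              st = cs.ends[s2]; ++s2;
            }
            (void) st;
            int a = alleles(cs.orig[s2] - 1, g - 1);
            G(i, j) += (a == 0) ? 1 : -1;
          }
        }
      }
    }
    if (i % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return G;
}
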