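// Extended haplotype homozygosity (EHH) decay and integrated EHH (iHH).
//
// Allele-specific EHH at marker distance d from a core site, among the n_c
// haplotypes carrying the core allele:
//   EHH(d) = sum_h n_h (n_h - 1) / (n_c (n_c - 1))
// over the distinct extended haplotypes (core..d).  Site-level EHH pools
// all haplotypes and normalizes the homozygosity sum by its value at the
// core, so both modes start at 1 and are non-increasing outward.
//
// iHH is the trapezoidal integral of the decay curve over physical
// distance (bp), after setting values below the cutoff to zero.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// sum over groups of n_g * (n_g - 1) after refining `grp` by column t of H
static double refine_and_sum(const IntegerMatrix& H,
                             const std::vector<int>& rows,
                             std::vector<int>& grp, int& ngroups, int t) {
    std::vector<int> remap(2 * ngroups, -1);
    std::vector<int> size;
    int nnew = 0;
    for (size_t i = 0; i < rows.size(); ++i) {
        const int key = grp[i] * 2 + H(rows[i], t);
        if (remap[key] < 0) {
            remap[key] = nnew++;
            size.push_back(0);
        }
        grp[i] = remap[key];
        size[grp[i]]++;
    }
    ngroups = nnew;
    double s = 0.0;
    for (int g = 0; g < nnew; ++g)
        s += (double)size[g] * (size[g] - 1);
    return s;
}

// initial grouping at the core; returns sum n_g (n_g - 1)
static double init_groups(const IntegerMatrix& H,
                          const std::vector<int>& rows,
                          std::vector<int>& grp, int& ngroups, int core,
                          bool site_level) {
    grp.assign(rows.size(), 0);
    ngroups = 1;
    if (site_level) {
        // split by core allele
        return refine_and_sum(H, rows, grp, ngroups, core);
    }
    // allele-specific: all carriers share the core allele -> one group
    double n = (double)rows.size();
    return n * (n - 1);
}

struct Decay {
    std::vector<int> idx;      // 0-based marker indices (excluding core)
    std::vector<double> ehh;
    std::string stop;          // "border", "cutoff", "gap", "degenerate"
};

static Decay extend(const IntegerMatrix& H, const std::vector<int>& rows,
                    const NumericVector& pos, int core, int dir,
                    bool site_level, double cutoff, double max_gap) {
    Decay out;
    std::vector<int> grp;
    int ngroups = 0;
    const double S0 = init_groups(H, rows, grp, ngroups, core, site_level);
    if (S0 <= 0) { out.stop = "degenerate"; return out; }
    const int m = H.ncol();
    int t = core + dir;
    double prev_pos = pos[core];
    out.stop = "border";
    while (t >= 0 && t < m) {
        if (max_gap > 0 && std::abs(pos[t] - prev_pos) > max_gap) {
            out.stop = "gap";
            break;
        }
        const double S = refine_and_sum(H, rows, grp, ngroups, t);
        const double e = S / S0;
        out.idx.push_back(t);
        out.ehh.push_back(e);
        if (e < cutoff) { out.stop = "cutoff"; break; }
        prev_pos = pos[t];
        t += dir;
    }
    return out;
}

// [[Rcpp::export(name = ".ehh_decay", rng = false)]]
List ehh_decay(const IntegerMatrix& H, const int core1,
               const int allele,       // -1 = site-level, else 0/1
               const NumericVector& pos,
               const double cutoff, const double max_gap) {
    const int core = core1 - 1;
    const bool site_level = (allele < 0);
    std::vector<int> rows;
    for (int i = 0; i < H.nrow(); ++i)
        if (site_level || H(i, core) == allele) rows.push_back(i);
    if (!site_level && rows.size() < 2)
        stop("allele-specific EHH needs >= 2 carrier haplotypes");
    Decay L = extend(H, rows, pos, core, -1, site_level, cutoff, max_gap);
    Decay R = extend(H, rows, pos, core, +1, site_level, cutoff, max_gap);

    const int nl = L.idx.size(), nr = R.idx.size();
    IntegerVector idx(nl + 1 + nr);
    NumericVector ehh(nl + 1 + nr);
    for (int i = 0; i < nl; ++i) {      // left side, ascending position
        idx[nl - 1 - i] = L.idx[i] + 1;
        ehh[nl - 1 - i] = L.ehh[i];
    }
    idx[nl] = core + 1;
    ehh[nl] = 1.0;
    for (int i = 0; i < nr; ++i) {
        idx[nl + 1 + i] = R.idx[i] + 1;
        ehh[nl + 1 + i] = R.ehh[i];
    }
    return List::create(_["index"] = idx, _["ehh"] = ehh,
                        _["n_hap"] = (int)rows.size(),
                        _["stop_left"] = L.stop, _["stop_right"] = R.stop);
}

// trapezoid with the below-cutoff-to-zero rule, one direction
static double side_area(const NumericVector& pos, int core, const Decay& d,
                        double cutoff) {
    double area = 0.0, pe = 1.0, pp = pos[core];
    for (size_t i = 0; i < d.idx.size(); ++i) {
        double e = d.ehh[i] < cutoff ? 0.0 : d.ehh[i];
        const double w = std::abs(pos[d.idx[i]] - pp);
        area += 0.5 * (pe + e) * w;
        pe = e;
        pp = pos[d.idx[i]];
    }
    return area;
}

// site-level iHH at every marker (the XP-EHH substrate)
// [[Rcpp::export(name = ".site_ihh_all", rng = false)]]
List site_ihh_all(const IntegerMatrix& H, const NumericVector& pos,
                  const double cutoff, const double max_gap) {
    const int m = H.ncol();
    NumericVector ihh(m);
    LogicalVector border(m), degenerate(m);
    std::vector<int> rows(H.nrow());
    for (int i = 0; i < H.nrow(); ++i) rows[i] = i;
    for (int j = 0; j < m; ++j) {
        Decay L = extend(H, rows, pos, j, -1, true, cutoff, max_gap);
        Decay R = extend(H, rows, pos, j, +1, true, cutoff, max_gap);
        if (L.stop == "degenerate" || R.stop == "degenerate") {
            ihh[j] = 0.0;
            degenerate[j] = true;
            continue;
        }
        ihh[j] = side_area(pos, j, L, cutoff) + side_area(pos, j, R, cutoff);
        border[j] = (L.stop == "border") || (R.stop == "border");
    }
    return List::create(_["ihh"] = ihh, _["border"] = border,
                        _["degenerate"] = degenerate);
}
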