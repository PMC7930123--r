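#include <Rcpp.h>
using namespace Rcpp;

// Minimum-image convention for one displacement component (orthorhombic box).
static inline double mic(double d, double L) {
    return d - L * std::round(d / L);
}

// Per-frame residue-by-lipid contact flags.
//
// coords: numeric array [n_frames x n_particles x 3] (Angstrom)
// box:    numeric matrix [n_frames x 3]
// res_groups / lip_groups: lists of 1-based particle index vectors
// cutoff: contact cutoff in Angstrom
//
// Returns a logical array [n_res x n_lip x n_frames]: TRUE when any particle
// of the residue group is within cutoff (minimum image) of any particle of
// the lipid group in that frame.
// [[Rcpp::export]]
LogicalVector cpp_contact_flags(NumericVector coords, NumericMatrix box,
                                List res_groups, List lip_groups,
                                double cutoff) {
    IntegerVector dims = coords.attr("dim");
    const int nf = dims[0], np = dims[1];
    const int nr = res_groups.size(), nl = lip_groups.size();
    const double cut2 = cutoff * cutoff;
    const double *C = REAL(coords);

    std::vector< std::vector<int> > rg(nr), lg(nl);
    for (int r = 0; r < nr; ++r) {
        IntegerVector v = res_groups[r];
        rg[r].assign(v.begin(), v.end());
        for (size_t i = 0; i < rg[r].size(); ++i) rg[r][i] -= 1;
    }
    for (int l = 0; l < nl; ++l) {
        IntegerVector v = lip_groups[l];
        lg[l].assign(v.begin(), v.end());
        for (size_t i = 0; i < lg[l].size(); ++i) lg[l][i] -= 1;
    }

    LogicalVector out(Dimension(nr, nl, nf));
    int *O = LOGICAL(out);
    const R_xlen_t stride = (R_xlen_t)nf * np;  // frame-major per axis

    for (int f = 0; f < nf; ++f) {
        const double Lx = box(f, 0), Ly = box(f, 1), Lz = box(f, 2);
        for (int l = 0; l < nl; ++l) {
            const std::vector<int> &lp = lg[l];
            for (int r = 0; r < nr; ++r) {
                const std::vector<int> &rp = rg[r];
                bool hit = false;
                for (size_t a = 0; a < rp.size() && !hit; ++a) {
                    const double ax = C[f + (R_xlen_t)nf * rp[a]];
                    const double ay = C[f + (R_xlen_t)nf * rp[a] + stride];
                    const double az = C[f + (R_xlen_t)nf * rp[a] + 2 * stride];
                    for (size_t b = 0; b < lp.size(); ++b) {
                        const double dx = mic(ax - C[f + (R_xlen_t)nf * lp[b]], Lx);
                        const double dy = mic(ay - C[f + (R_xlen_t)nf * lp[b] + stride], Ly);
                        const double dz = mic(az - C[f + (R_xlen_t)nf * lp[b] + 2 * stride], Lz);
                        if (dx * dx + dy * dy + dz * dz <= cut2) { hit = true; break; }
                    }
                }
                O[(R_xlen_t)f * nr * nl + (R_xlen_t)l * nr + r] = hit;
            }
        }
    }
    return out;
}

// Longest TRUE run along the third (frame) axis of an [nr x nl x nf]
// logical array; returns an integer matrix [nr x nl] of run lengths.
// [[Rcpp::export]]
IntegerMatrix cpp_longest_run(LogicalVector flags) {
    IntegerVector dims = flags.attr("dim");
    const int nr = dims[0], nl = dims[1], nf = dims[2];
    const int *F = LOGICAL(flags);
    IntegerMatrix out(nr, nl);
    for (int l = 0; l < nl; ++l) {
        for (int r = 0; r < nr; ++r) {
            int best = 0, cur = 0;
            for (int f = 0; f < nf; ++f) {
                if (F[(R_xlen_t)f * nr * nl + (R_xlen_t)l * nr + r]) {
                    if (++cur > best) best = cur;
                } else cur = 0;
            }
            out(r, l) = best;
        }
    }
    return out;
}

// Nearest reference point (periodic x-y distance) for every cell of an
// nx-by-ny grid over a box of size Lx-by-Ly. refs: matrix [m x 2] of
// reference x/y. Ties go to the lowest reference index (stable order).
// Returns 1-based reference indices per cell, in column-major (x fastest).
// [[Rcpp::export]]
IntegerVector cpp_grid_nearest(int nx, int ny, double Lx, double Ly,
                               NumericMatrix refs) {
    const int m = refs.nrow();
    IntegerVector out(nx * ny);
    const double hx = Lx / nx, hy = Ly / ny;
    for (int j = 0; j < ny; ++j) {
        const double cy = (j + 0.5) * hy;
        for (int i = 0; i < nx; ++i) {
            const double cx = (i + 0.5) * hx;
            double best = R_PosInf;
            int who = 0;
            for (int k = 0; k < m; ++k) {
                const double dx = mic(cx - refs(k, 0), Lx);
                const double dy = mic(cy - refs(k, 1), Ly);
                const double d2 = dx * dx + dy * dy;
                if (d2 < best) { best = d2; who = k; }
            }
            out[j * nx + i] = who + 1;
        }
    }
    return out;
}
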