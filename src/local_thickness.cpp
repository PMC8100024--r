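#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Felzenszwalb-Huttenlocher lower-envelope 1D squared distance transform.
// f holds squared distances on entry (INFV where unknown), d receives the
// transform. Large-but-finite INFV keeps the parabola intersections finite.
static const double INFV = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
    int k = 0;
    v[0] = 0;
    z[0] = -INFV;
    z[1] = INFV;
    for (int q = 1; q < n; q++) {
        double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                   (2.0 * q - 2.0 * v[k]);
        while (s <= z[k]) {
            k--;
            s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                (2.0 * q - 2.0 * v[k]);
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INFV;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        while (z[k + 1] < q) k++;
        double dq = (double)(q - v[k]);
        d[q] = dq * dq + f[v[k]];
    }
}

// Squared Euclidean distance (in voxel units) from every voxel to the nearest
// background (phase == 0) voxel centre. The volume is padded with one layer
// of virtual background outside every face, the usual convention for bounded
// scans: a structure cut by the domain face is bounded by it.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector phase, IntegerVector dim) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    // pass 1: along x (virtual background at both line ends)
    {
        std::vector<double> f(nx + 2), d(nx + 2);
        std::vector<int> v(nx + 2);
        std::vector<double> z(nx + 3);
        f[0] = 0.0;
        f[nx + 1] = 0.0;
        for (int kz = 0; kz < nz; kz++) {
            for (int ky = 0; ky < ny; ky++) {
                R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
                for (int i = 0; i < nx; i++)
                    f[i + 1] = phase[base + i] ? INFV : 0.0;
                dt1d(f, d, nx + 2, v, z);
                for (int i = 0; i < nx; i++) out[base + i] = d[i + 1];
            }
        }
    }
    // pass 2: along y
    {
        std::vector<double> f(ny + 2), d(ny + 2);
        std::vector<int> v(ny + 2);
        std::vector<double> z(ny + 3);
        f[0] = 0.0;
        f[ny + 1] = 0.0;
        for (int kz = 0; kz < nz; kz++) {
            for (int ix = 0; ix < nx; ix++) {
                R_xlen_t base = (R_xlen_t)kz * nx * ny + ix;
                for (int j = 0; j < ny; j++)
                    f[j + 1] = out[base + (R_xlen_t)j * nx];
                dt1d(f, d, ny + 2, v, z);
                for (int j = 0; j < ny; j++)
                    out[base + (R_xlen_t)j * nx] = d[j + 1];
            }
        }
    }
    // pass 3: along z
    if (nz > 1) {
        std::vector<double> f(nz + 2), d(nz + 2);
        std::vector<int> v(nz + 2);
        std::vector<double> z(nz + 3);
        f[0] = 0.0;
        f[nz + 1] = 0.0;
        const R_xlen_t stride = (R_xlen_t)nx * ny;
        for (int ky = 0; ky < ny; ky++) {
            for (int ix = 0; ix < nx; ix++) {
                R_xlen_t base = (R_xlen_t)ky * nx + ix;
                for (int k = 0; k < nz; k++)
                    f[k + 1] = out[base + (R_xlen_t)k * stride];
                dt1d(f, d, nz + 2, v, z);
                for (int k = 0; k < nz; k++)
                    out[base + (R_xlen_t)k * stride] = d[k + 1];
            }
        }
    }
    return out;
}

// Maximal-inscribed-sphere local thickness (distance ridge + sphere painting).
// For every phase voxel, the diameter (voxel units) of the largest sphere that
// contains the voxel and fits inside the phase. Sphere radius at a centre c is
// the centre-to-centre distance to the nearest background voxel minus half a
// voxel (the phase boundary is taken midway between centres). Returns 0 for
// non-phase voxels.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector phase, IntegerVector dim) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector d2 = cpp_edt_sq(phase, dim);
    NumericVector th(n);

    std::vector<double> r(n, 0.0);
    bool any_inf = false;
    for (R_xlen_t i = 0; i < n; i++) {
        if (!phase[i]) continue;
        if (d2[i] >= INFV / 2) {
            any_inf = true;
            r[i] = -1.0; // unreachable from any boundary
        } else {
            r[i] = std::sqrt(d2[i]) - 0.5;
            if (r[i] < 0.5) r[i] = 0.5; // isolated voxel: one-voxel sphere
        }
    }

    // distance-ridge extraction: drop voxels whose sphere lies entirely inside
    // a 26-neighbour's sphere (r_q >= r_p + |p - q|); containment chains end
    // at kept local maxima, so no coverage is lost.
    std::vector<R_xlen_t> ridge;
    ridge.reserve(n / 16 + 1);
    const double nbd[3] = {1.0, std::sqrt(2.0), std::sqrt(3.0)};
    for (int kz = 0; kz < nz; kz++) {
        for (int ky = 0; ky < ny; ky++) {
            for (int ix = 0; ix < nx; ix++) {
                R_xlen_t p = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx + ix;
                if (!phase[p] || r[p] < 0) continue;
                bool contained = false;
                for (int dz = -1; dz <= 1 && !contained; dz++) {
                    int zq = kz + dz;
                    if (zq < 0 || zq >= nz) continue;
                    for (int dy = -1; dy <= 1 && !contained; dy++) {
                        int yq = ky + dy;
                        if (yq < 0 || yq >= ny) continue;
                        for (int dx = -1; dx <= 1; dx++) {
                            if (dx == 0 && dy == 0 && dz == 0) continue;
                            int xq = ix + dx;
                            if (xq < 0 || xq >= nx) continue;
                            R_xlen_t q = (R_xlen_t)zq * nx * ny +
                                         (R_xlen_t)yq * nx + xq;
                            if (!phase[q] || r[q] < 0) continue;
                            double dist = nbd[std::abs(dx) + std::abs(dy) +
                                              std::abs(dz) - 1];
                            if (r[q] + 1e-9 >= r[p] + dist) {
                                contained = true;
                                break;
                            }
                        }
                    }
                }
                if (!contained) ridge.push_back(p);
            }
        }
    }

    // paint spheres, largest first, writing the diameter onto covered voxels
    std::sort(ridge.begin(), ridge.end(), [&](R_xlen_t a, R_xlen_t b) {
        return r[a] > r[b];
    });
    for (R_xlen_t ri = 0; ri < (R_xlen_t)ridge.size(); ri++) {
        R_xlen_t p = ridge[ri];
        double rp = r[p];
        double D = 2.0 * rp;
        // sphere extent uses the centre-to-centre radius (rp + 0.5): a voxel
        // whose centre the inscribed ball reaches counts as covered, while
        // the reported diameter stays boundary-corrected
        double rc = rp + 0.5;
        int cx = (int)(p % nx);
        int cy = (int)((p / nx) % ny);
        int cz = (int)(p / ((R_xlen_t)nx * ny));
        int R = (int)std::floor(rc + 1e-9);
        for (int dz = -R; dz <= R; dz++) {
            int zq = cz + dz;
            if (zq < 0 || zq >= nz) continue;
            double rem_z = rc * rc - (double)dz * dz;
            if (rem_z < 0) continue;
            for (int dy = -R; dy <= R; dy++) {
                int yq = cy + dy;
                if (yq < 0 || yq >= ny) continue;
                double rem = rem_z - (double)dy * dy;
                if (rem < 0) continue;
                int dxm = (int)std::floor(std::sqrt(rem) + 1e-9);
                int x0 = std::max(0, cx - dxm);
                int x1 = std::min(nx - 1, cx + dxm);
                R_xlen_t base = (R_xlen_t)zq * nx * ny + (R_xlen_t)yq * nx;
                for (int xq = x0; xq <= x1; xq++) {
                    R_xlen_t q = base + xq;
                    if (phase[q] && th[q] < D) th[q] = D;
                }
            }
        }
    }

    if (any_inf) {
        for (R_xlen_t i = 0; i < n; i++)
            if (phase[i] && r[i] < 0) th[i] = NA_REAL;
    }
    // every phase voxel is covered at least by its own sphere
    for (R_xlen_t i = 0; i < n; i++)
        if (phase[i] && r[i] >= 0 && th[i] < 2.0 * r[i]) th[i] = 2.0 * r[i];
    return th;
}
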