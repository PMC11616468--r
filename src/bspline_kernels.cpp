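#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Cubic B-spline basis, pieces B0..B3 on the local parameter u in [0,1).
static inline void bspline_weights(double u, double *w) {
    const double u2 = u * u, u3 = u2 * u;
    w[0] = (1.0 - 3.0 * u + 3.0 * u2 - u3) / 6.0;
    w[1] = (3.0 * u3 - 6.0 * u2 + 4.0) / 6.0;
    w[2] = (-3.0 * u3 + 3.0 * u2 + 3.0 * u + 1.0) / 6.0;
    w[3] = u3 / 6.0;
}

// Per-axis lookup tables: for each voxel index along an axis, the lattice
// cell index and the four basis weights. Valid because the image grid and
// the control lattice are both axis-aligned and uniform.
struct AxisTable {
    std::vector<int> cell;
    std::vector<double> w; // 4 per voxel
};

static AxisTable build_axis_table(int n, double img_o, double img_sp,
                                  double ctl_o, double ctl_sp, int nc) {
    AxisTable t;
    t.cell.resize(n);
    t.w.resize(4 * n);
    for (int i = 0; i < n; ++i) {
        double s = (img_o + i * img_sp - ctl_o) / ctl_sp;
        int c = (int)std::floor(s);
        double u = s - c;
        // guard against floating-point sitting exactly on the last knot
        if (c > nc - 3) { c = nc - 3; u = s - c; }
        if (c < 1) { c = 1; u = s - c; }
        if (u < -1e-6 || u > 1.0 + 1e-6)
            stop("voxel outside lattice support (axis table)");
        if (u < 0.0) u = 0.0;
        if (u > 1.0) u = 1.0;
        t.cell[i] = c;
        bspline_weights(u, &t.w[4 * i]);
    }
    return t;
}

// Evaluate a control-point lattice as a dense displacement field on an
// image grid. coef has dim (ncx, ncy, ncz, 3); result (nx, ny, nz, 3), mm.
// [[Rcpp::export]]
NumericVector cpp_evaluate_lattice(NumericVector coef, IntegerVector ncdim,
                                   NumericVector ctl_origin, NumericVector ctl_spacing,
                                   NumericVector img_origin, NumericVector img_spacing,
                                   IntegerVector img_shape) {
    const int ncx = ncdim[0], ncy = ncdim[1], ncz = ncdim[2];
    const int nx = img_shape[0], ny = img_shape[1], nz = img_shape[2];
    AxisTable tx = build_axis_table(nx, img_origin[0], img_spacing[0], ctl_origin[0], ctl_spacing[0], ncx);
    AxisTable ty = build_axis_table(ny, img_origin[1], img_spacing[1], ctl_origin[1], ctl_spacing[1], ncy);
    AxisTable tz = build_axis_table(nz, img_origin[2], img_spacing[2], ctl_origin[2], ctl_spacing[2], ncz);

    NumericVector out((R_xlen_t)nx * ny * nz * 3);
    const double *cf = coef.begin();
    double *o = out.begin();
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
    const R_xlen_t ncp = (R_xlen_t)ncx * ncy * ncz;

    for (int iz = 0; iz < nz; ++iz) {
        const int cz = tz.cell[iz];
        const double *wz = &tz.w[4 * iz];
        for (int iy = 0; iy < ny; ++iy) {
            const int cy = ty.cell[iy];
            const double *wy = &ty.w[4 * iy];
            for (int ix = 0; ix < nx; ++ix) {
                const int cx = tx.cell[ix];
                const double *wx = &tx.w[4 * ix];
                double u0 = 0.0, u1 = 0.0, u2 = 0.0;
                for (int c = 0; c < 4; ++c) {
                    const R_xlen_t kz = (R_xlen_t)(cz - 1 + c) * ncx * ncy;
                    for (int b = 0; b < 4; ++b) {
                        const R_xlen_t kyz = kz + (R_xlen_t)(cy - 1 + b) * ncx;
                        const double wzy = wz[c] * wy[b];
                        for (int a = 0; a < 4; ++a) {
                            const R_xlen_t k = kyz + (cx - 1 + a);
                            const double w = wzy * wx[a];
                            u0 += w * cf[k];
                            u1 += w * cf[k + ncp];
                            u2 += w * cf[k + 2 * ncp];
                        }
                    }
                }
                const R_xlen_t v = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
                o[v] = u0;
                o[v + nvox] = u1;
                o[v + 2 * nvox] = u2;
            }
        }
    }
    return out;
}

// Trilinear sample of img at continuous voxel coordinates (qx,qy,qz),
// nearest-edge clamped; optionally returns the spatial gradient in
// index units through g[3].
static inline double trilinear(const double *img, int nx, int ny, int nz,
                               double qx, double qy, double qz, double *g) {
    if (qx < 0) qx = 0; if (qx > nx - 1) qx = nx - 1;
    if (qy < 0) qy = 0; if (qy > ny - 1) qy = ny - 1;
    if (qz < 0) qz = 0; if (qz > nz - 1) qz = nz - 1;
    int i0 = (int)std::floor(qx); if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
    int j0 = (int)std::floor(qy); if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
    int k0 = (int)std::floor(qz); if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
    const double tx = qx - i0, ty = qy - j0, tz = qz - k0;
    const int i1 = nx > 1 ? i0 + 1 : i0;
    const int j1 = ny > 1 ? j0 + 1 : j0;
    const int k1 = nz > 1 ? k0 + 1 : k0;
    #define IMG(i, j, k) img[(R_xlen_t)(i) + (R_xlen_t)nx * ((j) + (R_xlen_t)ny * (k))]
    const double c000 = IMG(i0, j0, k0), c100 = IMG(i1, j0, k0);
    const double c010 = IMG(i0, j1, k0), c110 = IMG(i1, j1, k0);
    const double c001 = IMG(i0, j0, k1), c101 = IMG(i1, j0, k1);
    const double c011 = IMG(i0, j1, k1), c111 = IMG(i1, j1, k1);
    #undef IMG
    const double c00 = c000 + tx * (c100 - c000);
    const double c10 = c010 + tx * (c110 - c010);
    const double c01 = c001 + tx * (c101 - c001);
    const double c11 = c011 + tx * (c111 - c011);
    const double c0 = c00 + ty * (c10 - c00);
    const double c1 = c01 + ty * (c11 - c01);
    if (g) {
        const double dx00 = c100 - c000, dx10 = c110 - c010;
        const double dx01 = c101 - c001, dx11 = c111 - c011;
        g[0] = (dx00 + ty * (dx10 - dx00)) * (1 - tz) + (dx01 + ty * (dx11 - dx01)) * tz;
        const double dy0 = c10 - c00, dy1 = c11 - c01;
        g[1] = dy0 + tz * (dy1 - dy0);
        g[2] = c1 - c0;
    }
    return c0 + tz * (c1 - c0);
}

// Mean squared intensity difference between fixed and moving sampled at the
// displaced positions of a dense field (dim (nx,ny,nz,3), mm, world axes).
// [[Rcpp::export]]
double cpp_ssd_field(NumericVector fixed_img, NumericVector moving_img,
                     IntegerVector shape, NumericVector field,
                     NumericVector origin, NumericVector spacing) {
    const int nx = shape[0], ny = shape[1], nz = shape[2];
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
    const double *f = fixed_img.begin(), *m = moving_img.begin(), *u = field.begin();
    double acc = 0.0;
    for (R_xlen_t v = 0; v < nvox; ++v) {
        const int ix = (int)(v % nx);
        const int iy = (int)((v / nx) % ny);
        const int iz = (int)(v / ((R_xlen_t)nx * ny));
        const double qx = ix + u[v] / spacing[0];
        const double qy = iy + u[v + nvox] / spacing[1];
        const double qz = iz + u[v + 2 * nvox] / spacing[2];
        const double r = trilinear(m, nx, ny, nz, qx, qy, qz, nullptr) - f[v];
        acc += r * r;
    }
    return acc / (double)nvox;
}

// Objective (mean SSD + bend_weight * bending proxy) and, optionally, its
// analytic gradient with respect to the lattice coefficients.
// [[Rcpp::export]]
List cpp_ssd_grad_lattice(NumericVector fixed_img, NumericVector moving_img,
                          IntegerVector shape, NumericVector coef, IntegerVector ncdim,
                          NumericVector ctl_origin, NumericVector ctl_spacing,
                          NumericVector img_origin, NumericVector img_spacing,
                          double bend_weight, bool want_grad) {
    const int ncx = ncdim[0], ncy = ncdim[1], ncz = ncdim[2];
    const int nx = shape[0], ny = shape[1], nz = shape[2];
    AxisTable tx = build_axis_table(nx, img_origin[0], img_spacing[0], ctl_origin[0], ctl_spacing[0], ncx);
    AxisTable ty = build_axis_table(ny, img_origin[1], img_spacing[1], ctl_origin[1], ctl_spacing[1], ncy);
    AxisTable tz = build_axis_table(nz, img_origin[2], img_spacing[2], ctl_origin[2], ctl_spacing[2], ncz);

    const R_xlen_t ncp = (R_xlen_t)ncx * ncy * ncz;
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
    const double *cf = coef.begin();
    const double *f = fixed_img.begin(), *m = moving_img.begin();
    NumericVector grad(want_grad ? 3 * ncp : 1);
    double *gr = grad.begin();
    if (want_grad) std::fill(gr, gr + 3 * ncp, 0.0);

    double ssd = 0.0;
    double gmv[3];
    for (int iz = 0; iz < nz; ++iz) {
        const int cz = tz.cell[iz];
        const double *wz = &tz.w[4 * iz];
        for (int iy = 0; iy < ny; ++iy) {
            const int cy = ty.cell[iy];
            const double *wy = &ty.w[4 * iy];
            for (int ix = 0; ix < nx; ++ix) {
                const int cx = tx.cell[ix];
                const double *wx = &tx.w[4 * ix];
                double u0 = 0.0, u1 = 0.0, u2 = 0.0;
                for (int c = 0; c < 4; ++c) {
                    const R_xlen_t kz = (R_xlen_t)(cz - 1 + c) * ncx * ncy;
                    for (int b = 0; b < 4; ++b) {
                        const R_xlen_t kyz = kz + (R_xlen_t)(cy - 1 + b) * ncx;
                        const double wzy = wz[c] * wy[b];
                        for (int a = 0; a < 4; ++a) {
                            const R_xlen_t k = kyz + (cx - 1 + a);
                            const double w = wzy * wx[a];
                            u0 += w * cf[k];
                            u1 += w * cf[k + ncp];
                            u2 += w * cf[k + 2 * ncp];
                        }
                    }
                }
                const double qx = ix + u0 / img_spacing[0];
                const double qy = iy + u1 / img_spacing[1];
                const double qz = iz + u2 / img_spacing[2];
                const R_xlen_t v = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
                const double mv = trilinear(m, nx, ny, nz, qx, qy, qz, want_grad ? gmv : nullptr);
                const double r = mv - f[v];
                ssd += r * r;
                if (want_grad) {
                    // d(metric)/du in world mm: trilinear gradient is in
                    // index units, divide by spacing.
                    const double f0 = 2.0 * r * gmv[0] / img_spacing[0] / (double)nvox;
                    const double f1 = 2.0 * r * gmv[1] / img_spacing[1] / (double)nvox;
                    const double f2 = 2.0 * r * gmv[2] / img_spacing[2] / (double)nvox;
                    if (f0 != 0.0 || f1 != 0.0 || f2 != 0.0) {
                        for (int c = 0; c < 4; ++c) {
                            const R_xlen_t kz = (R_xlen_t)(cz - 1 + c) * ncx * ncy;
                            for (int b = 0; b < 4; ++b) {
                                const R_xlen_t kyz = kz + (R_xlen_t)(cy - 1 + b) * ncx;
                                const double wzy = wz[c] * wy[b];
                                for (int a = 0; a < 4; ++a) {
                                    const R_xlen_t k = kyz + (cx - 1 + a);
                                    const double w = wzy * wx[a];
                                    gr[k] += w * f0;
                                    gr[k + ncp] += w * f1;
                                    gr[k + 2 * ncp] += w * f2;
                                }
                            }
                        }
                    }
                }
            }
        }
    }
    ssd /= (double)nvox;

    // Bending-energy proxy: mean squared second difference of the
    // coefficients along each lattice axis, scaled by control spacing^2.
    double bend = 0.0;
    const double norm = 1.0 / (3.0 * (double)ncp);
    for (int comp = 0; comp < 3; ++comp) {
        const double *cc = cf + comp * ncp;
        double *gg = want_grad ? gr + comp * ncp : nullptr;
        for (int iz = 0; iz < ncz; ++iz) {
            for (int iy = 0; iy < ncy; ++iy) {
                for (int ix = 0; ix < ncx; ++ix) {
                    const R_xlen_t k = (R_xlen_t)ix + (R_xlen_t)ncx * (iy + (R_xlen_t)ncy * iz);
                    const int strides[3] = {1, ncx, ncx * ncy};
                    const int pos[3] = {ix, iy, iz};
                    const int nax[3] = {ncx, ncy, ncz};
                    for (int ax = 0; ax < 3; ++ax) {
                        if (pos[ax] < 1 || pos[ax] > nax[ax] - 2) continue;
                        const double h2 = ctl_spacing[ax] * ctl_spacing[ax];
                        const double d2 = (cc[k - strides[ax]] - 2.0 * cc[k] + cc[k + strides[ax]]) / h2;
                        bend += norm * d2 * d2;
                        if (want_grad) {
                            const double gfac = bend_weight * norm * 2.0 * d2 / h2;
                            gg[k - strides[ax]] += gfac;
                            gg[k] += -2.0 * gfac;
                            gg[k + strides[ax]] += gfac;
                        }
                    }
                }
            }
        }
    }

    return List::create(_["value"] = ssd + bend_weight * bend,
                        _["ssd"] = ssd, _["bend"] = bend,
                        _["grad"] = want_grad ? (SEXP)grad : R_NilValue);
}

// Separable Gaussian smoothing (reflected boundaries) followed by integer
// decimation; used to build the multi-resolution image pyramid.
// [[Rcpp::export]]
NumericVector cpp_smooth_downsample(NumericVector img, IntegerVector shape,
                                    NumericVector sigma_vox, IntegerVector factor) {
    const int dims[3] = {shape[0], shape[1], shape[2]};
    std::vector<double> buf(img.begin(), img.end());
    std::vector<double> tmp(buf.size());

    for (int ax = 0; ax < 3; ++ax) {
        const double sg = sigma_vox[ax];
        if (sg <= 0) continue;
        const int rad = (int)std::ceil(3.0 * sg);
        std::vector<double> kern(2 * rad + 1);
        double ks = 0;
        for (int t = -rad; t <= rad; ++t) {
            kern[t + rad] = std::exp(-0.5 * t * t / (sg * sg));
            ks += kern[t + rad];
        }
        for (auto &k : kern) k /= ks;
        const int n = dims[ax];
        const R_xlen_t stride = ax == 0 ? 1 : (ax == 1 ? dims[0] : (R_xlen_t)dims[0] * dims[1]);
        const R_xlen_t total = (R_xlen_t)dims[0] * dims[1] * dims[2];
        const R_xlen_t nlines = total / n;
        for (R_xlen_t line = 0; line < nlines; ++line) {
            // base index of this line
            R_xlen_t base;
            if (ax == 0) base = line * n;
            else if (ax == 1) {
                const R_xlen_t x = line % dims[0], z = line / dims[0];
                base = x + (R_xlen_t)dims[0] * dims[1] * z;
            } else {
                base = line;
            }
            for (int i = 0; i < n; ++i) {
                double acc = 0;
                for (int t = -rad; t <= rad; ++t) {
                    int j = i + t;
                    if (j < 0) j = -j;                 // reflect
                    if (j > n - 1) j = 2 * (n - 1) - j;
                    if (j < 0) j = 0;
                    acc += kern[t + rad] * buf[base + (R_xlen_t)j * stride];
                }
                tmp[base + (R_xlen_t)i * stride] = acc;
            }
        }
        std::swap(buf, tmp);
    }

    const int fx = factor[0], fy = factor[1], fz = factor[2];
    const int ox = (dims[0] - 1) / fx + 1, oy = (dims[1] - 1) / fy + 1, oz = (dims[2] - 1) / fz + 1;
    NumericVector out((R_xlen_t)ox * oy * oz);
    double *o = out.begin();
    for (int iz = 0; iz < oz; ++iz)
        for (int iy = 0; iy < oy; ++iy)
            for (int ix = 0; ix < ox; ++ix)
                o[(R_xlen_t)ix + (R_xlen_t)ox * (iy + (R_xlen_t)oy * iz)] =
                    buf[(R_xlen_t)ix * fx + (R_xlen_t)dims[0] * ((R_xlen_t)iy * fy + (R_xlen_t)dims[1] * ((R_xlen_t)iz * fz))];
    out.attr("dim") = IntegerVector::create(ox, oy, oz);
    return out;
}
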