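#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Minimal (Kabsch-optimal) RMSD between two conformations via the largest
// eigenvalue of Horn's 4x4 quaternion matrix, found by Newton iteration on
// its characteristic quartic (the matrix is traceless, so the quartic has
// no cubic term). Avoids an SVD per pair, which matters for the ~n^2/2
// pairs needed by GROMOS clustering of long trajectories.

// coefficients of lambda^4 + c2*lambda^2 + c1*lambda + c0 from the traceless
// symmetric 4x4 matrix K (Newton's identities on power sums of eigenvalues)
static void char_poly(const double K[4][4], double &c2, double &c1, double &c0) {
    double K2[4][4];
    for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
            double s = 0.0;
            for (int k = 0; k < 4; ++k) s += K[i][k] * K[k][j];
            K2[i][j] = s;
        }
    double p2 = 0.0, p3 = 0.0, p4 = 0.0;
    for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
            p2 += K[i][j] * K[i][j];
            p3 += K2[i][j] * K[j][i];
            p4 += K2[i][j] * K2[j][i];
        }
    c2 = -0.5 * p2;
    c1 = -p3 / 3.0;
    c0 = 0.25 * (0.5 * p2 * p2 - p4);
}

// squared minimal RMSD between centered frames a and b (interleaved xyz),
// with Ga, Gb their squared norms
static double qcp_msd(const double *a, const double *b, int natoms,
                      double Ga, double Gb) {
    double Sxx = 0, Sxy = 0, Sxz = 0, Syx = 0, Syy = 0, Syz = 0,
           Szx = 0, Szy = 0, Szz = 0;
    for (int i = 0; i < natoms; ++i) {
        const double ax = a[3 * i], ay = a[3 * i + 1], az = a[3 * i + 2];
        const double bx = b[3 * i], by = b[3 * i + 1], bz = b[3 * i + 2];
        Sxx += ax * bx; Sxy += ax * by; Sxz += ax * bz;
        Syx += ay * bx; Syy += ay * by; Syz += ay * bz;
        Szx += az * bx; Szy += az * by; Szz += az * bz;
    }
    double K[4][4];
    K[0][0] = Sxx + Syy + Szz;
    K[0][1] = K[1][0] = Syz - Szy;
    K[0][2] = K[2][0] = Szx - Sxz;
    K[0][3] = K[3][0] = Sxy - Syx;
    K[1][1] = Sxx - Syy - Szz;
    K[1][2] = K[2][1] = Sxy + Syx;
    K[1][3] = K[3][1] = Szx + Sxz;
    K[2][2] = -Sxx + Syy - Szz;
    K[2][3] = K[3][2] = Syz + Szy;
    K[3][3] = -Sxx - Syy + Szz;

    const double E0 = 0.5 * (Ga + Gb);
    if (E0 < 1e-15) return 0.0;

    double c2, c1, c0;
    char_poly(K, c2, c1, c0);

    // Newton from above: E0 >= lambda_max always
    double lam = E0;
    for (int it = 0; it < 60; ++it) {
        double lam2 = lam * lam;
        double P = lam2 * lam2 + c2 * lam2 + c1 * lam + c0;
        double dP = 4.0 * lam2 * lam + 2.0 * c2 * lam + c1;
        if (dP == 0.0) break;
        double step = P / dP;
        lam -= step;
        if (std::fabs(step) < 1e-12 * (std::fabs(E0) + 1e-12)) break;
    }
    double msd = (Ga + Gb - 2.0 * lam) / natoms;
    return msd > 0.0 ? msd : 0.0;
}

// center frames in place (rows of xyz), return per-frame squared norms
static std::vector<double> center_frames(NumericMatrix &xyz, int natoms) {
    const int n = xyz.nrow();
    std::vector<double> G(n);
    for (int f = 0; f < n; ++f) {
        double cx = 0, cy = 0, cz = 0;
        for (int i = 0; i < natoms; ++i) {
            cx += xyz(f, 3 * i);
            cy += xyz(f, 3 * i + 1);
            cz += xyz(f, 3 * i + 2);
        }
        cx /= natoms; cy /= natoms; cz /= natoms;
        double g = 0;
        for (int i = 0; i < natoms; ++i) {
            double x = xyz(f, 3 * i) - cx;
            double y = xyz(f, 3 * i + 1) - cy;
            double z = xyz(f, 3 * i + 2) - cz;
            xyz(f, 3 * i) = x; xyz(f, 3 * i + 1) = y; xyz(f, 3 * i + 2) = z;
            g += x * x + y * y + z * z;
        }
        G[f] = g;
    }
    return G;
}

// copy row f of xyz into contiguous buffer
static void row_to_buf(const NumericMatrix &xyz, int f, std::vector<double> &buf) {
    const int m = xyz.ncol();
    for (int j = 0; j < m; ++j) buf[j] = xyz(f, j);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_pairwise_rmsd")]]
NumericMatrix cpp_pairwise_rmsd(NumericMatrix xyz_in) {
    NumericMatrix xyz = clone(xyz_in);
    const int n = xyz.nrow();
    const int natoms = xyz.ncol() / 3;
    if (xyz.ncol() % 3 != 0) stop("coordinate row length must be a multiple of 3");
    std::vector<double> G = center_frames(xyz, natoms);
    NumericMatrix D(n, n);
    std::vector<double> bi(xyz.ncol()), bj(xyz.ncol());
    for (int i = 0; i < n; ++i) {
        row_to_buf(xyz, i, bi);
        for (int j = i + 1; j < n; ++j) {
            row_to_buf(xyz, j, bj);
            double r = std::sqrt(qcp_msd(&bi[0], &bj[0], natoms, G[i], G[j]));
            D(i, j) = r;
            D(j, i) = r;
        }
    }
    return D;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_gromos")]]
List cpp_gromos(NumericMatrix xyz_in, double cutoff) {
    NumericMatrix xyz = clone(xyz_in);
    const int n = xyz.nrow();
    const int natoms = xyz.ncol() / 3;
    if (n < 1) stop("empty input");
    if (xyz.ncol() % 3 != 0) stop("coordinate row length must be a multiple of 3");
    std::vector<double> G = center_frames(xyz, natoms);

    // adjacency (neighbor within cutoff), including self
    std::vector<uint8_t> adj((size_t)n * n, 0);
    const double c2 = cutoff * cutoff;
    std::vector<double> bi(xyz.ncol()), bj(xyz.ncol());
    for (int i = 0; i < n; ++i) {
        adj[(size_t)i * n + i] = 1;
        row_to_buf(xyz, i, bi);
        for (int j = i + 1; j < n; ++j) {
            row_to_buf(xyz, j, bj);
            if (qcp_msd(&bi[0], &bj[0], natoms, G[i], G[j]) <= c2) {
                adj[(size_t)i * n + j] = 1;
                adj[(size_t)j * n + i] = 1;
            }
        }
        if (i % 256 == 0) Rcpp::checkUserInterrupt();
    }

    IntegerVector labels(n, 0);
    std::vector<int> centers;
    std::vector<uint8_t> active(n, 1);
    int remaining = n, cl = 0;
    while (remaining > 0) {
        // neighbor counts among active frames; tie -> lowest frame index
        int best = -1, bestCount = -1;
        for (int i = 0; i < n; ++i) {
            if (!active[i]) continue;
            int cnt = 0;
            const uint8_t *row = &adj[(size_t)i * n];
            for (int j = 0; j < n; ++j)
                if (active[j] && row[j]) ++cnt;
            if (cnt > bestCount) { bestCount = cnt; best = i; }
        }
        ++cl;
        centers.push_back(best + 1);
        const uint8_t *row = &adj[(size_t)best * n];
        for (int j = 0; j < n; ++j) {
            if (active[j] && row[j]) {
                labels[j] = cl;
                active[j] = 0;
                --remaining;
            }
        }
        Rcpp::checkUserInterrupt();
    }
    return List::create(_["labels"] = labels,
                        _["centers"] = wrap(centers));
}

//' @noRd
// [[Rcpp::export(name = ".cpp_rmsd_to_ref")]]
NumericVector cpp_rmsd_to_ref(NumericMatrix xyz_in, NumericVector ref_in) {
    NumericMatrix xyz = clone(xyz_in);
    const int n = xyz.nrow();
    const int natoms = xyz.ncol() / 3;
    if ((int)ref_in.size() != xyz.ncol())
        stop("reference length does not match frame length");
    std::vector<double> G = center_frames(xyz, natoms);
    // center reference
    std::vector<double> ref(ref_in.begin(), ref_in.end());
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < natoms; ++i) {
        cx += ref[3 * i]; cy += ref[3 * i + 1]; cz += ref[3 * i + 2];
    }
    cx /= natoms; cy /= natoms; cz /= natoms;
    double Gr = 0;
    for (int i = 0; i < natoms; ++i) {
        ref[3 * i] -= cx; ref[3 * i + 1] -= cy; ref[3 * i + 2] -= cz;
        Gr += ref[3 * i] * ref[3 * i] + ref[3 * i + 1] * ref[3 * i + 1] +
              ref[3 * i + 2] * ref[3 * i + 2];
    }
    NumericVector out(n);
    std::vector<double> bi(xyz.ncol());
    for (int f = 0; f < n; ++f) {
        row_to_buf(xyz, f, bi);
        out[f] = std::sqrt(qcp_msd(&bi[0], &ref[0], natoms, G[f], Gr));
    }
    return out;
}
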