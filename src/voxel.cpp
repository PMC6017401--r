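// Voxel kernels for the solvent-excluded-surface (SES) grid:
//  - signed distance-to-van-der-Waals field over atom spheres
//  - exact Euclidean distance transform (squared, separable) with
//    nearest-site tracking, used for the morphological probe closure
//  - flood fill / connected components on voxel masks
//  - marching-tetrahedra iso-surface triangulation (6-tet cube split)
//  - brute-force nearest-atom lookup for triangle centroids

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <queue>

using namespace Rcpp;

namespace {
inline size_t lin(int ix, int iy, int iz, int nx, int ny) {
    return (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz);
}
const double BIG = 1e20;
}

// field[v] = min over atoms of (dist(voxel centre, atom centre) - radius),
// capped above at `cap`.  Atoms only touch voxels within radius + cap.
// [[Rcpp::export]]
NumericVector cpp_atom_field(IntegerVector dims, NumericVector origin,
                             double spacing, NumericMatrix coords,
                             NumericVector radii, double cap) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    NumericVector field((size_t)nx * ny * nz, cap);
    int na = coords.nrow();
    for (int a = 0; a < na; ++a) {
        double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
        double r = radii[a];
        double reach = r + cap;
        int ix0 = std::max(0, (int)std::ceil((cx - reach - origin[0]) / spacing));
        int ix1 = std::min(nx - 1, (int)std::floor((cx + reach - origin[0]) / spacing));
        int iy0 = std::max(0, (int)std::ceil((cy - reach - origin[1]) / spacing));
        int iy1 = std::min(ny - 1, (int)std::floor((cy + reach - origin[1]) / spacing));
        int iz0 = std::max(0, (int)std::ceil((cz - reach - origin[2]) / spacing));
        int iz1 = std::min(nz - 1, (int)std::floor((cz + reach - origin[2]) / spacing));
        for (int iz = iz0; iz <= iz1; ++iz) {
            double dz = origin[2] + iz * spacing - cz;
            for (int iy = iy0; iy <= iy1; ++iy) {
                double dy = origin[1] + iy * spacing - cy;
                double dyz = dy * dy + dz * dz;
                for (int ix = ix0; ix <= ix1; ++ix) {
                    double dx = origin[0] + ix * spacing - cx;
                    double d = std::sqrt(dx * dx + dyz) - r;
                    size_t id = lin(ix, iy, iz, nx, ny);
                    if (d < field[id]) field[id] = d;
                }
            }
        }
    }
    return field;
}

namespace {
// 1D squared distance transform (Felzenszwalb & Huttenlocher) with
// argmin-site propagation.  f/fs: input costs and their sites; d/ds out.
void dt1d(const std::vector<double>& f, const std::vector<int>& fs,
          std::vector<double>& d, std::vector<int>& ds) {
    int n = (int)f.size();
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -BIG;
    z[1] = BIG;
    for (int q = 1; q < n; ++q) {
        double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k]))
                   / (2.0 * q - 2.0 * v[k]);
        while (s <= z[k]) {
            k--;
            s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k]))
                / (2.0 * q - 2.0 * v[k]);
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = BIG;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) k++;
        double dq = (double)q - v[k];
        d[q] = dq * dq + f[v[k]];
        ds[q] = fs[v[k]];
    }
}
}  // namespace

// Exact Euclidean distance transform from the TRUE voxels of `seed`.
// Returns distances in physical units (spacing-scaled) and, for every
// voxel, the linear (0-based) index of its nearest seed voxel (-1 when no
// seed exists).
// [[Rcpp::export]]
List cpp_edt_sites(LogicalVector seed, IntegerVector dims, double spacing) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    size_t nv = (size_t)nx * ny * nz;
    std::vector<double> cost(nv);
    std::vector<int> site(nv);
    for (size_t i = 0; i < nv; ++i) {
        cost[i] = seed[i] ? 0.0 : BIG;
        site[i] = seed[i] ? (int)i : -1;
    }
    // pass along x
    {
        std::vector<double> f(nx), d(nx);
        std::vector<int> fs(nx), ds(nx);
        for (int iz = 0; iz < nz; ++iz)
            for (int iy = 0; iy < ny; ++iy) {
                for (int ix = 0; ix < nx; ++ix) {
                    size_t id = lin(ix, iy, iz, nx, ny);
                    f[ix] = cost[id];
                    fs[ix] = site[id];
                }
                dt1d(f, fs, d, ds);
                for (int ix = 0; ix < nx; ++ix) {
                    size_t id = lin(ix, iy, iz, nx, ny);
                    cost[id] = d[ix];
                    site[id] = ds[ix];
                }
            }
    }
    // pass along y
    {
        std::vector<double> f(ny), d(ny);
        std::vector<int> fs(ny), ds(ny);
        for (int iz = 0; iz < nz; ++iz)
            for (int ix = 0; ix < nx; ++ix) {
                for (int iy = 0; iy < ny; ++iy) {
                    size_t id = lin(ix, iy, iz, nx, ny);
                    f[iy] = cost[id];
                    fs[iy] = site[id];
                }
                dt1d(f, fs, d, ds);
                for (int iy = 0; iy < ny; ++iy) {
                    size_t id = lin(ix, iy, iz, nx, ny);
                    cost[id] = d[iy];
                    site[id] = ds[iy];
                }
            }
    }
    // pass along z
    {
        std::vector<double> f(nz), d(nz);
        std::vector<int> fs(nz), ds(nz);
        for (int iy = 0; iy < ny; ++iy)
            for (int ix = 0; ix < nx; ++ix) {
                for (int iz = 0; iz < nz; ++iz) {
                    size_t id = lin(ix, iy, iz, nx, ny);
                    f[iz] = cost[id];
                    fs[iz] = site[id];
                }
                dt1d(f, fs, d, ds);
                for (int iz = 0; iz < nz; ++iz) {
                    size_t id = lin(ix, iy, iz, nx, ny);
                    cost[id] = d[iz];
                    site[id] = ds[iz];
                }
            }
    }
    NumericVector dist(nv);
    IntegerVector sites(nv);
    for (size_t i = 0; i < nv; ++i) {
        dist[i] = (cost[i] >= BIG) ? R_PosInf : spacing * std::sqrt(cost[i]);
        sites[i] = site[i];
    }
    return List::create(_["dist"] = dist, _["site"] = sites);
}

namespace {
void neighbourOffsets(int conn, int nx, int ny, int nz,
                      std::vector<std::array<int,3> >& offs) {
    offs.clear();
    if (conn == 6) {
        int o[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int i = 0; i < 6; ++i)
            offs.push_back({o[i][0], o[i][1], o[i][2]});
    } else {
        for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx)
                    if (dx || dy || dz) offs.push_back({dx, dy, dz});
    }
}
}  // namespace

// Voxels of `open` reachable from any open voxel on a grid face.
// [[Rcpp::export]]
LogicalVector cpp_flood_boundary(LogicalVector open, IntegerVector dims,
                                 int conn) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    size_t nv = (size_t)nx * ny * nz;
    LogicalVector reached(nv, false);
    std::vector<std::array<int,3> > offs;
    neighbourOffsets(conn, nx, ny, nz, offs);
    std::queue<std::array<int,3> > q;
    for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy)
            for (int ix = 0; ix < nx; ++ix) {
                if (ix != 0 && ix != nx - 1 && iy != 0 && iy != ny - 1 &&
                    iz != 0 && iz != nz - 1)
                    continue;
                size_t id = lin(ix, iy, iz, nx, ny);
                if (open[id] && !reached[id]) {
                    reached[id] = true;
                    q.push({ix, iy, iz});
                }
            }
    while (!q.empty()) {
        std::array<int,3> c = q.front();
        q.pop();
        for (size_t k = 0; k < offs.size(); ++k) {
            int ix = c[0] + offs[k][0], iy = c[1] + offs[k][1],
                iz = c[2] + offs[k][2];
            if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
                continue;
            size_t id = lin(ix, iy, iz, nx, ny);
            if (open[id] && !reached[id]) {
                reached[id] = true;
                q.push({ix, iy, iz});
            }
        }
    }
    return reached;
}

// Connected-component labels (1..K in scan order) of `mask`.
// [[Rcpp::export]]
IntegerVector cpp_components(LogicalVector mask, IntegerVector dims,
                             int conn) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    size_t nv = (size_t)nx * ny * nz;
    IntegerVector labels(nv, 0);
    std::vector<std::array<int,3> > offs;
    neighbourOffsets(conn, nx, ny, nz, offs);
    int next = 0;
    for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy)
            for (int ix = 0; ix < nx; ++ix) {
                size_t id0 = lin(ix, iy, iz, nx, ny);
                if (!mask[id0] || labels[id0] != 0) continue;
                next++;
                labels[id0] = next;
                std::queue<std::array<int,3> > q;
                q.push({ix, iy, iz});
                while (!q.empty()) {
                    std::array<int,3> c = q.front();
                    q.pop();
                    for (size_t k = 0; k < offs.size(); ++k) {
                        int jx = c[0] + offs[k][0], jy = c[1] + offs[k][1],
                            jz = c[2] + offs[k][2];
                        if (jx < 0 || jy < 0 || jz < 0 || jx >= nx ||
                            jy >= ny || jz >= nz)
                            continue;
                        size_t id = lin(jx, jy, jz, nx, ny);
                        if (mask[id] && labels[id] == 0) {
                            labels[id] = next;
                            q.push({jx, jy, jz});
                        }
                    }
                }
            }
    return labels;
}

namespace {
// cube corner c (0..7): bit0 -> +x, bit1 -> +y, bit2 -> +z
const int TETS[6][4] = {
    {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
    {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};

struct MeshAcc {
    std::vector<double> vx, vy, vz;
    std::vector<int> tri;   // 3 vertex ids (0-based) per triangle
    std::vector<int> cell;  // linear cube index per triangle
    int addVert(const double p[3]) {
        vx.push_back(p[0]); vy.push_back(p[1]); vz.push_back(p[2]);
        return (int)vx.size() - 1;
    }
    void addTri(int a, int b, int c, int cube) {
        tri.push_back(a); tri.push_back(b); tri.push_back(c);
        cell.push_back(cube);
    }
};

inline void interp(const double a[3], const double b[3], double fa, double fb,
                   double iso, double out[3]) {
    double t = (iso - fa) / (fb - fa);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + t * (b[i] - a[i]);
}
}  // namespace

// Marching tetrahedra over a scalar field at level `iso`.  Each grid cube
// is split into six tetrahedra sharing the main diagonal; the surface
// within each tetrahedron is the linear-interpolation iso-surface.
// "Inside" is field > iso.  Returns vertices (A), 1-based triangle vertex
// indices, and the 1-based linear index of the generating cube.
// [[Rcpp::export]]
List cpp_march_tet(NumericVector field, IntegerVector dims,
                   NumericVector origin, double spacing, double iso) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    MeshAcc mesh;
    double p[8][3];
    double f[8];
    for (int iz = 0; iz + 1 < nz; ++iz)
        for (int iy = 0; iy + 1 < ny; ++iy)
            for (int ix = 0; ix + 1 < nx; ++ix) {
                bool anyIn = false, anyOut = false;
                for (int c = 0; c < 8; ++c) {
                    int cx = ix + (c & 1), cy = iy + ((c >> 1) & 1),
                        cz = iz + ((c >> 2) & 1);
                    f[c] = field[lin(cx, cy, cz, nx, ny)];
                    p[c][0] = origin[0] + cx * spacing;
                    p[c][1] = origin[1] + cy * spacing;
                    p[c][2] = origin[2] + cz * spacing;
                    if (f[c] > iso) anyIn = true; else anyOut = true;
                }
                if (!anyIn || !anyOut) continue;
                int cube = (int)lin(ix, iy, iz, nx, ny) + 1;
                for (int t = 0; t < 6; ++t) {
                    int vi[4] = {TETS[t][0], TETS[t][1], TETS[t][2],
                                 TETS[t][3]};
                    int in[4], out[4], ni = 0, no = 0;
                    for (int c = 0; c < 4; ++c) {
                        if (f[vi[c]] > iso) in[ni++] = vi[c];
                        else out[no++] = vi[c];
                    }
                    if (ni == 0 || ni == 4) continue;
                    double q[4][3];
                    if (ni == 1 || ni == 3) {
                        int apex = (ni == 1) ? in[0] : out[0];
                        int* base = (ni == 1) ? out : in;
                        for (int c = 0; c < 3; ++c)
                            interp(p[apex], p[base[c]], f[apex], f[base[c]],
                                   iso, q[c]);
                        int a = mesh.addVert(q[0]);
                        int b = mesh.addVert(q[1]);
                        int cc = mesh.addVert(q[2]);
                        mesh.addTri(a, b, cc, cube);
                    } else {  // 2 in, 2 out: quad -> two triangles
                        interp(p[in[0]], p[out[0]], f[in[0]], f[out[0]], iso, q[0]);
                        interp(p[in[0]], p[out[1]], f[in[0]], f[out[1]], iso, q[1]);
                        interp(p[in[1]], p[out[1]], f[in[1]], f[out[1]], iso, q[2]);
                        interp(p[in[1]], p[out[0]], f[in[1]], f[out[0]], iso, q[3]);
                        int a = mesh.addVert(q[0]);
                        int b = mesh.addVert(q[1]);
                        int cc = mesh.addVert(q[2]);
                        int d = mesh.addVert(q[3]);
                        mesh.addTri(a, b, cc, cube);
                        mesh.addTri(a, cc, d, cube);
                    }
                }
            }
    int nvert = (int)mesh.vx.size();
    NumericMatrix verts(nvert, 3);
    for (int i = 0; i < nvert; ++i) {
        verts(i, 0) = mesh.vx[i];
        verts(i, 1) = mesh.vy[i];
        verts(i, 2) = mesh.vz[i];
    }
    int ntri = (int)mesh.cell.size();
    IntegerMatrix tris(ntri, 3);
    IntegerVector cells(ntri);
    for (int i = 0; i < ntri; ++i) {
        tris(i, 0) = mesh.tri[3 * i] + 1;
        tris(i, 1) = mesh.tri[3 * i + 1] + 1;
        tris(i, 2) = mesh.tri[3 * i + 2] + 1;
        cells[i] = mesh.cell[i];
    }
    return List::create(_["vertices"] = verts, _["triangles"] = tris,
                        _["cell"] = cells);
}

// For each query point, the 1-based row index of the nearest reference
// point (ties: lowest index).
// [[Rcpp::export]]
IntegerVector cpp_nearest_point(NumericMatrix query, NumericMatrix ref) {
    int nq = query.nrow(), nr = ref.nrow();
    if (nr == 0) stop("no reference points");
    IntegerVector out(nq);
    for (int i = 0; i < nq; ++i) {
        double best = R_PosInf;
        int bi = 0;
        for (int j = 0; j < nr; ++j) {
            double dx = query(i, 0) - ref(j, 0);
            double dy = query(i, 1) - ref(j, 1);
            double dz = query(i, 2) - ref(j, 2);
            double d = dx * dx + dy * dy + dz * dz;
            if (d < best) { best = d; bi = j; }
        }
        out[i] = bi + 1;
    }
    return out;
}
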