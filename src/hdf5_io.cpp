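// Minimal HDF5 bindings: read/write one named 3D dataset. The connectomics
// convention stores volumes as (z, y, x) row-major; the R wrappers handle the
// transpose to R's column-major arrays.

#include <Rcpp.h>
#include <hdf5.h>
#include <string>
#include <vector>

using namespace Rcpp;

static void silence_hdf5() {
  H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
}

// [[Rcpp::export(name = ".h5_read3d")]]
List h5_read3d(std::string path, std::string key) {
  silence_hdf5();
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  hid_t dset = H5Dopen2(file, key.c_str(), H5P_DEFAULT);
  if (dset < 0) { H5Fclose(file); stop("dataset '%s' not found in '%s'", key.c_str(), path.c_str()); }

  hid_t space = H5Dget_space(dset);
  int ndim = H5Sget_simple_extent_ndims(space);
  if (ndim != 3) {
    H5Sclose(space); H5Dclose(dset); H5Fclose(file);
    stop("expected 3 dimensions, dataset '%s' has %d", key.c_str(), ndim);
  }
  hsize_t dims[3];
  H5Sget_simple_extent_dims(space, dims, NULL);
  size_t n = (size_t)dims[0] * dims[1] * dims[2];

  hid_t dtype = H5Dget_type(dset);
  H5T_class_t cls = H5Tget_class(dtype);
  size_t tsize = H5Tget_size(dtype);
  bool is_int = (cls == H5T_INTEGER);
  bool is_unsigned = is_int && (H5Tget_sign(dtype) == H5T_SGN_NONE);
  double type_max = NA_REAL;
  if (is_int) {
    double bits = 8.0 * (double)tsize - (is_unsigned ? 0.0 : 1.0);
    type_max = std::pow(2.0, bits) - 1.0;
  }
  H5Tclose(dtype);

  NumericVector out((R_xlen_t)n);
  herr_t st = H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(out));
  H5Sclose(space); H5Dclose(dset); H5Fclose(file);
  if (st < 0) stop("HDF5 read failed for dataset '%s'", key.c_str());

  IntegerVector d(3);
  d[0] = (int)dims[0]; d[1] = (int)dims[1]; d[2] = (int)dims[2];
  return List::create(_["data"] = out, _["dims"] = d,
                      _["is_integer"] = is_int, _["type_max"] = type_max);
}

// data must already be in row-major order for dims (z, y, x).
// kind: "double" (float64), "uint8", "uint16", "uint32".
// [[Rcpp::export(name = ".h5_write3d")]]
void h5_write3d(std::string path, std::string key, NumericVector data,
                IntegerVector dims, std::string kind, bool overwrite) {
  silence_hdf5();
  hid_t file;
  if (overwrite) {
    file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  } else {
    file = H5Fopen(path.c_str(), H5F_ACC_RDWR, H5P_DEFAULT);
    if (file < 0) file = H5Fcreate(path.c_str(), H5F_ACC_EXCL, H5P_DEFAULT, H5P_DEFAULT);
  }
  if (file < 0) stop("cannot create HDF5 file '%s'", path.c_str());

  hsize_t d[3] = {(hsize_t)dims[0], (hsize_t)dims[1], (hsize_t)dims[2]};
  hid_t space = H5Screate_simple(3, d, NULL);
  hid_t ftype = H5T_NATIVE_DOUBLE;
  if (kind == "uint8") ftype = H5T_STD_U8LE;
  else if (kind == "uint16") ftype = H5T_STD_U16LE;
  else if (kind == "uint32") ftype = H5T_STD_U32LE;
  else if (kind != "double") { H5Sclose(space); H5Fclose(file); stop("unknown HDF5 kind '%s'", kind.c_str()); }

  // disable object-header timestamps so identical data yields identical files
  hid_t dcpl = H5Pcreate(H5P_DATASET_CREATE);
  H5Pset_obj_track_times(dcpl, 0);
  hid_t dset = H5Dcreate2(file, key.c_str(), ftype, space, H5P_DEFAULT, dcpl, H5P_DEFAULT);
  H5Pclose(dcpl);
  if (dset < 0) { H5Sclose(space); H5Fclose(file); stop("cannot create dataset '%s' (already exists?)", key.c_str()); }
  herr_t st = H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(data));
  H5Dclose(dset); H5Sclose(space); H5Fclose(file);
  if (st < 0) stop("HDF5 write failed for dataset '%s'", key.c_str());
}

// [[Rcpp::export(name = ".h5_has_dataset")]]
bool h5_has_dataset(std::string path, std::string key) {
  silence_hdf5();
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) return false;
  htri_t ex = H5Lexists(file, key.c_str(), H5P_DEFAULT);
  H5Fclose(file);
  return ex > 0;
}
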