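# Small in-code fixtures shared across test files.

# Build a detection data.frame from timestamp strings.
make_records <- function(times, species = "fox", site = "A", camera = "A_cam1",
                         lat = 54.6, lon = -5.9, group_size = 1L) {
  data.frame(species = species, site_id = site, camera_id = camera,
             timestamp = as.POSIXct(times, tz = "UTC"),
             latitude = lat, longitude = lon, group_size = group_size,
             stringsAsFactors = FALSE)
}

make_sites <- function(site_ids = "A", lat = 54.6, lon = -5.9, utc_offset = 0) {
  data.frame(site_id = site_ids, latitude = lat, longitude = lon,
             utc_offset = utc_offset, stringsAsFactors = FALSE)
}

# A fixed mid-latitude solar day with round sunrise/sunset, handy when the
# test controls the sun directly.
fixed_solar_day <- function(sunrise = 6, sunset = 20, date = "2015-07-01") {
  solar_day(as.Date(date), 54.6, -5.9, 0, sunrise = sunrise, sunset = sunset)
}
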